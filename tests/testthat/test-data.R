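test_that("CSV records round-trip through write and read, missing included", {
  df <- generate_synthetic(n = 40, missing_rate = 0.2, seed = 61)
  path <- withr::local_tempfile(fileext = ".csv")
  write_records(df, path)
  back <- read_records(path)
  expect_equal(back[paste0("q", 1:22)], df[paste0("q", 1:22)])
  expect_equal(back$dec, df$dec)
  expect_equal(back$id, seq_len(40))
})

test_that("malformed records are rejected with row and column context", {
  path <- withr::local_tempfile(fileext = ".csv")
  hdr <- paste(c(paste0("q", 1:22), "dec"), collapse = ",")
  ok <- paste(c(rep("1", 22), "0"), collapse = ",")
  bad_val <- paste(c("7", rep("1", 21), "0"), collapse = ",")
  writeLines(c(hdr, ok, bad_val), path)
  expect_error(read_records(path), "out of range.*q1.*row 2")
  bad_dec <- paste(c(rep("1", 22), ""), collapse = ",")
  writeLines(c(hdr, ok, bad_dec), path)
  expect_error(read_records(path), "missing decision")
  writeLines(c(hdr, paste(c("x", rep("1", 21), "1"), collapse = ",")), path)
  expect_error(read_records(path), "out of range")
})

test_that("fuzzification embeds answers as degenerate intervals", {
  df <- data.frame(matrix(3L, 1, 22)); names(df) <- paste0("q", 1:22)
  df$q2 <- 0L; df$q3 <- NA_integer_; df$dec <- 1L
  fz <- fuzzify(df)
  expect_equal(fz$lo[1, 1], 0.75); expect_equal(fz$hi[1, 1], 0.75)
  expect_equal(fz$lo[1, 2], 0); expect_equal(fz$hi[1, 2], 0)
  expect_equal(fz$lo[1, 3], 0); expect_equal(fz$hi[1, 3], 1)
  expect_equal(fz$dec, 1L)
  # idempotent on its output representation: re-embedding changes nothing
  expect_equal(fuzzify(df)$lo, fz$lo)
})

test_that("the synthetic generator pins counts, classes and reproducibility", {
  df <- generate_synthetic(seed = 71)
  expect_equal(nrow(df), 750)
  expect_equal(sum(df$dec == 1L), 249)
  miss <- mean(is.na(as.matrix(df[paste0("q", 1:22)])))
  expect_gt(miss, 0.03); expect_lt(miss, 0.07)
  df2 <- generate_synthetic(seed = 71)
  expect_identical(df, df2)
  small <- generate_synthetic(n = 10, positive_fraction = 0.5,
                              missing_rate = 0, seed = 72)
  expect_equal(sum(small$dec == 1L), 5)
  expect_false(anyNA(small[paste0("q", 1:22)]))
  expect_error(generate_synthetic(positive_fraction = 1.5), "positive_fraction")
})

test_that("risk and verification items move in opposite directions", {
  df <- generate_synthetic(n = 400, missing_rate = 0, seed = 73)
  risk <- rowMeans(df[paste0("q", 1:20)])
  verif <- rowMeans(df[paste0("q", 21:22)])
  expect_gt(mean(risk[df$dec == 1]), mean(risk[df$dec == 0]))
  expect_lt(mean(verif[df$dec == 1]), mean(verif[df$dec == 0]))
})

test_that("a trivial sum-score threshold separates the default classes", {
  df <- generate_synthetic(seed = 74)
  sc <- rowMeans(as.matrix(df[paste0("q", 1:20)]), na.rm = TRUE)
  thr <- mean(tapply(sc, df$dec, mean))
  acc <- mean((sc > thr) == (df$dec == 1L))
  expect_gt(acc, 0.8)
})

test_that("the stratified holdout preserves sizes and class fractions", {
  df <- generate_synthetic(seed = 81)
  sp <- split_records(df, split_plan("holdout_70_30", seed = 82))
  expect_equal(nrow(sp$train), 525)
  expect_equal(nrow(sp$test), 225)
  expect_equal(sum(sp$train$dec == 1L), round(249 * 0.7))
  expect_equal(length(intersect(sp$train$id, sp$test$id)), 0)
  sp2 <- split_records(df, split_plan("holdout_70_30", seed = 82))
  expect_identical(sp, sp2)
})

test_that("the NON-IID split has a balanced pool and the stated skews", {
  df <- generate_synthetic(seed = 83)
  sp <- split_records(df, split_plan("noniid_3clients", seed = 84))
  expect_equal(nrow(sp$test), 112)
  expect_equal(sum(sp$test$dec == 1L), 56)
  sizes <- vapply(sp$clients, nrow, 0L)
  expect_true(all(sizes == sizes[1]))
  mixes <- vapply(sp$clients, function(cl) mean(cl$dec == 1L), 0)
  expect_equal(mixes, c(0.5, 0.2, 0.8), tolerance = 0.02)
  # client 2 class-0:class-1 ratio about 4:1
  expect_equal(sum(sp$clients[[2]]$dec == 0) / sum(sp$clients[[2]]$dec == 1),
               4, tolerance = 0.1)
  # disjointness across all parts
  ids <- c(sp$test$id, unlist(lapply(sp$clients, `[[`, "id")), sp$unused$id)
  expect_equal(anyDuplicated(ids), 0)
  expect_setequal(ids, df$id)
})

test_that("infeasible splits fail with a shortfall message", {
  df <- generate_synthetic(n = 40, positive_fraction = 0.05, seed = 85)
  expect_error(split_records(df, split_plan("noniid_3clients", seed = 86)),
               "infeasible")
})

test_that("stratified k-fold covers the data with near-equal class shares", {
  df <- generate_synthetic(n = 200, seed = 87)
  folds <- split_records(df, split_plan("kfold_10", seed = 88))
  expect_length(folds, 10)
  expect_setequal(unlist(folds), seq_len(200))
  pos <- vapply(folds, function(f) sum(df$dec[f] == 1L), 0L)
  expect_lte(max(pos) - min(pos), 1L)
})
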