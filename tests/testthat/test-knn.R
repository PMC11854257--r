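make_record <- function(answers, dec = 0L, id = 1L) {
  df <- as.data.frame(matrix(answers, 1, 22)); names(df) <- paste0("q", 1:22)
  df$dec <- dec; df$id <- id
  df
}

test_that("object similarity is maximal for identical complete records", {
  cfg <- classifier_config()
  y <- iv(rep(0.5, 22))
  expect_equal(unclass(object_similarity(y, y, cfg)), unclass(iv(1, 1)))
  # crisp opposite answers: all 4 vs all 0
  a <- iv(rep(1, 22)); b <- iv(rep(0, 22))
  expect_equal(unclass(object_similarity(a, b, cfg)), unclass(iv(0, 0)))
})

test_that("a missing answer widens similarity from below only", {
  cfg <- classifier_config()
  y <- iv(rep(0.5, 22))
  x <- iv(c(0, rep(0.5, 21)), c(1, rep(0.5, 21)))  # one slot missing
  s <- object_similarity(y, x, cfg)
  # the optimistic possible family saturates on overlapping slots
  expect_equal(iv_hi(s), 1)
  # the standard family registers the epistemic loss from the missing slot
  cfg_std <- classifier_config(similarity = similarity_spec("standard"),
                               entropy = entropy_spec("standard"))
  s_std <- object_similarity(y, x, cfg_std)
  expect_lt(iv_lo(s_std), 1)
  set.seed(91)
  for (t in 1:50) {
    ans <- sample(0:4, 22, replace = TRUE)
    ymem <- iv(ans / 4)
    x1 <- ans; x1[sample(1:20, 1)] <- NA
    xlo <- ifelse(is.na(x1), 0, x1 / 4); xhi <- ifelse(is.na(x1), 1, x1 / 4)
    s_full <- object_similarity(ymem, iv(ans / 4), cfg)
    s_miss <- object_similarity(ymem, iv(xlo, xhi), cfg)
    expect_lte(iv_lo(s_miss), iv_lo(s_full) + 1e-12)
  }
})

test_that("an exact duplicate becomes its class representative with d = [1,1]", {
  train <- rbind(make_record(rep(2L, 22), dec = 0L, id = 1L),
                 make_record(rep(4L, 22), dec = 1L, id = 2L),
                 make_record(c(rep(0L, 11), rep(1L, 11)), dec = 0L, id = 3L))
  fit <- iv_knn(train, classifier_config(k = 1))
  y <- fuzzify(make_record(rep(2L, 22)))
  reps <- nearest_by_class(iv(y$lo[1, ], y$hi[1, ]), fit)
  expect_equal(reps[["0"]]$index, 1L)
  expect_equal(unclass(reps[["0"]]$similarity), unclass(iv(1, 1)))
})

test_that("equally similar neighbours are separated by lower entropy", {
  # two class-1 records equidistant from the query: one classical (entropy
  # [0,0]), one with missing answers (wide entropy) -> classical picked
  q <- rep(0L, 22)
  classical <- make_record(rep(0L, 22), dec = 1L, id = 1L)
  missing <- make_record(rep(0L, 22), dec = 1L, id = 2L)
  missing[paste0("q", 1:10)] <- NA_integer_
  train <- rbind(classical, missing)
  cfg <- classifier_config(k = 2)
  fit <- iv_knn(train, cfg)
  fy <- fuzzify(make_record(q))
  reps <- nearest_by_class(iv(fy$lo[1, ], fy$hi[1, ]), fit)
  expect_equal(reps[["1"]]$index, 1L)
  expect_identical(c(iv_lo(reps[["1"]]$entropy), iv_hi(reps[["1"]]$entropy)),
                   c(0, 0))
})

test_that("the decision cascade follows its five rules", {
  cfg2 <- classifier_config(order = order_spec("partial2"))
  expect_equal(classify_intervals(iv(0.3, 0.4), iv(0.8, 0.9), cfg2)$label, "1")
  expect_equal(classify_intervals(iv(0.55, 0.6), iv(0.4, 0.6), cfg2)$label, "0")
  nd <- classify_intervals(iv(0.4, 0.6), iv(0.4, 0.6), cfg2)
  expect_equal(nd$label, "ND")
  # neutral rule: mutually possible evidence, only d1 reaches [0.5,0.5]
  cfgp <- classifier_config(order = order_spec("possible"))
  r <- classify_intervals(iv(0.2, 0.4), iv(0.3, 0.8), cfgp)
  expect_equal(r$label, "1")
  expect_equal(r$rule, "neutral")
  # width rule: same midpoint straddling neutral both ways
  r2 <- classify_intervals(iv(0.1, 0.9), iv(0.45, 0.55), cfg2)
  expect_equal(r2$label, "1")
  expect_equal(r2$rule, "width")
  # single-class inputs
  expect_equal(classify_intervals(NULL, iv(0.2, 0.3), cfg2)$label, "1")
  expect_equal(classify_intervals(iv(0.2, 0.3), NULL, cfg2)$label, "0")
  expect_error(classify_intervals(NULL, NULL, cfg2), "at least one")
})

test_that("the verification override fires only as specified", {
  cfg <- classifier_config()
  rec <- function(a21, a22) {
    lo <- rep(0.5, 22); hi <- rep(0.5, 22)
    if (is.na(a21)) { lo[21] <- 0; hi[21] <- 1 } else lo[21] <- hi[21] <- a21 / 4
    if (is.na(a22)) { lo[22] <- 0; hi[22] <- 1 } else lo[22] <- hi[22] <- a22 / 4
    iv(lo, hi)
  }
  p0 <- list(label = "0")
  expect_true(verify_decision(rec(1, 4), p0, cfg)$verification_fired)
  expect_equal(verify_decision(rec(1, 4), p0, cfg)$label, "1")
  expect_false(verify_decision(rec(3, 4), p0, cfg)$verification_fired)
  # missing verification answers never trigger
  expect_false(verify_decision(rec(NA, NA), p0, cfg)$verification_fired)
  # a risk label passes through untouched
  p1 <- verify_decision(rec(0, 0), list(label = "1"), cfg)
  expect_equal(p1$label, "1")
  expect_false(p1$verification_fired)
  # abstention is overridden too
  expect_equal(verify_decision(rec(0, 4), list(label = "ND"), cfg)$label, "1")
})

test_that("predictions are deterministic and evidence is populated", {
  df <- generate_synthetic(n = 80, seed = 92)
  fit <- iv_knn(df[1:60, ], classifier_config(k = 3))
  p1 <- predict(fit, df[61:80, ])
  p2 <- predict(fit, df[61:80, ])
  expect_identical(p1, p2)
  expect_true(all(p1$label %in% c("0", "1", "ND")))
  expect_true(all(!is.na(p1$d0_lo) | !is.na(p1$d1_lo)))
})

test_that("predict matches the scalar reference pipeline on toy data", {
  set.seed(93)
  kinds <- c("partial2", "admissible", "possible", "necessary")
  fams <- c("standard", "possible", "necessary")
  for (t in 1:25) {
    kind <- kinds[(t %% 4) + 1]
    fam <- fams[(t %% 3) + 1]
    strategy <- if (t %% 2 == 0) "per_class_k" else "global_k"
    k <- sample(c(1, 3, 5), 1)
    train <- make_toy_records(sample(3:8, 1))
    test <- make_toy_records(3)
    cfg <- classifier_config(k = k, order = order_spec(kind),
                             similarity = similarity_spec(fam),
                             entropy = entropy_spec(fam),
                             condition_attributes = 1:4,
                             neighbor_strategy = strategy)
    fit <- iv_knn(train, cfg)
    got <- predict(fit, test)$label
    want <- vapply(seq_len(3), function(i)
      o_predict(test[i, ], train, k, kind, fam, strategy, cond_attrs = 1:4),
      "")
    expect_equal(got, want,
                 info = sprintf("kind=%s fam=%s strat=%s k=%d", kind, fam,
                                strategy, k))
  }
})
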