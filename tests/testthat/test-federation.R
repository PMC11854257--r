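test_that("confusion counts penalize abstentions as misclassifications", {
  cc <- confusion(c("1", "0", "1", "0"), c(1, 0, 0, 1))
  expect_equal(unlist(cc[c("TP", "TN", "FP", "FN")]), c(TP = 1, TN = 1, FP = 1, FN = 1))
  cc2 <- confusion(c("ND", "ND"), c(1, 0))
  expect_equal(cc2$FN, 1); expect_equal(cc2$FP, 1)
  expect_equal(cc2$TP + cc2$TN, 0)
  cc0 <- confusion(character(0), integer(0))
  expect_equal(unlist(cc0[c("TP", "TN", "FP", "FN")]),
               c(TP = 0, TN = 0, FP = 0, FN = 0))
  expect_error(confusion("1", c(1, 0)), "equal length")
})

test_that("metrics follow the printed formulas and guard zero denominators", {
  m <- classification_metrics(structure(list(TP = 3, TN = 4, FP = 1, FN = 2),
                                        class = "confusion"))
  expect_equal(unname(m["ACC"]), 0.7)
  expect_equal(unname(m["SENS"]), 0.6)
  expect_equal(unname(m["SPEC"]), 0.8)
  expect_equal(unname(m["PREC"]), 0.75)
  m2 <- classification_metrics(structure(list(TP = 0, TN = 5, FP = 0, FN = 2),
                                         class = "confusion"))
  expect_true(is.na(m2["PREC"]))
  expect_true("PREC" %in% attr(m2, "undefined"))
  m3 <- classification_metrics(confusion(c("1", "0"), c(1, 0)))
  expect_equal(unname(m3["ACC"]), 1)
})

test_that("accuracy is invariant under swapping the positive convention", {
  set.seed(101)
  truth <- sample(0:1, 50, replace = TRUE)
  pred <- as.character(sample(0:1, 50, replace = TRUE))
  m <- classification_metrics(confusion(pred, truth))
  swapped <- classification_metrics(
    confusion(as.character(1L - as.integer(pred)), 1L - truth))
  expect_equal(unname(m["ACC"]), unname(swapped["ACC"]))
  expect_equal(unname(m["SENS"]), unname(swapped["SPEC"]))
  expect_equal(unname(m["SPEC"]), unname(swapped["SENS"]))
})

fake_pred <- function(labels, e0 = NA, e1 = NA) {
  n <- length(labels)
  data.frame(id = seq_len(n), label = labels,
             e0_lo = rep(if (length(e0) == 2) e0[1] else NA_real_, n),
             e0_hi = rep(if (length(e0) == 2) e0[2] else NA_real_, n),
             e1_lo = rep(if (length(e1) == 2) e1[1] else NA_real_, n),
             e1_hi = rep(if (length(e1) == 2) e1[2] else NA_real_, n),
             stringsAsFactors = FALSE)
}

test_that("federated voting takes pluralities and breaks ties by entropy", {
  ord <- order_spec("partial2")
  # plain plurality
  v <- federated_vote(list(fake_pred("1"), fake_pred("1"), fake_pred("0")), ord)
  expect_equal(v, "1")
  # abstentions are excluded from the vote
  v2 <- federated_vote(list(fake_pred("ND"), fake_pred("ND"), fake_pred("0")), ord)
  expect_equal(v2, "0")
  # all abstain
  expect_equal(federated_vote(list(fake_pred("ND"), fake_pred("ND")), ord), "ND")
  # tie: the class-1 voter carries the lower representative entropy
  v3 <- federated_vote(list(fake_pred("1", e1 = c(0.1, 0.2)),
                            fake_pred("0", e0 = c(0.4, 0.6))), ord)
  expect_equal(v3, "1")
  v4 <- federated_vote(list(fake_pred("1", e1 = c(0.5, 0.7)),
                            fake_pred("0", e0 = c(0.1, 0.2))), ord)
  expect_equal(v4, "0")
  # a single client is the identity on labels
  expect_equal(federated_vote(list(fake_pred(c("1", "0", "ND"))), ord),
               c("1", "0", "ND"))
  expect_error(federated_vote(list()), "no client")
})

test_that("the decision rule gates adoption on the efficiency comparison", {
  truth <- c(1, 1, 0, 0)
  local_preds <- list(c("1", "1", "0", "0"),   # strong client, ACC 1
                      c("0", "0", "0", "0"),   # weak client, ACC 0.5
                      c("1", "1", "1", "1"))   # weak client, ACC 0.5
  fed <- c("1", "1", "0", "1")                 # ACC 0.75
  local_efs <- c(1, 0.5, 0.5)
  dr <- decision_rule("ACC", local_efs, 0.75, local_preds, fed, truth)
  expect_equal(dr$adopted, c(FALSE, TRUE, TRUE))
  expect_equal(dr$final[[1]], local_preds[[1]])
  expect_equal(dr$final[[2]], fed)
  expect_equal(dr$metrics$ACC, c(1, 0.75, 0.75))
  # nobody below the federation: nothing changes
  dr2 <- decision_rule("ACC", c(0.9, 0.8), 0.8,
                       local_preds[1:2], fed, truth)
  expect_equal(dr2$adopted, c(FALSE, FALSE))
})

test_that("scenario runs are deterministic and correctly shaped", {
  df <- generate_synthetic(n = 200, seed = 111)
  cfg <- classifier_config(k = 3)
  r1 <- run_scenario("s2", data = df, config = cfg, repetitions = 2, seed = 5)
  expect_s3_class(r1, "scenario_run")
  expect_equal(nrow(r1$metrics), 6)  # 3 clients x 2 reps
  expect_setequal(unique(r1$metrics$unit), paste0("client", 1:3))
  r1b <- run_scenario("s2", data = df, config = cfg, repetitions = 2, seed = 5)
  expect_identical(r1$metrics, r1b$metrics)
  r0 <- run_scenario("s1", data = df, config = cfg, repetitions = 1, seed = 6)
  expect_equal(unique(r0$metrics$unit), "central")
})

test_that("post-rule efficiency equals max(local, federated) by recomputation", {
  df <- generate_synthetic(n = 260, seed = 112)
  cfg <- classifier_config(k = 3)
  r <- run_scenario("s3", data = df, config = cfg, repetitions = 2, seed = 7)
  m <- r$metrics
  for (rep_i in unique(m$rep)) {
    fed <- m$ACC[m$rep == rep_i & m$unit == "federated"]
    for (ci in 1:3) {
      loc <- m$ACC[m$rep == rep_i & m$unit == paste0("client", ci)]
      post <- m$ACC[m$rep == rep_i & m$unit == paste0("postrule_client", ci)]
      expect_equal(post, max(loc, fed))
    }
  }
})
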