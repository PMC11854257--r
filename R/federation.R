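#' Confusion counts with abstention penalty
#'
#' Tallies TP/TN/FP/FN for binary screening outcomes. An abstention
#' (`"ND"`) is penalized as a misclassification: it counts as a false
#' negative when the true class is 1 and as a false positive when the true
#' class is 0 — abstentions are never silently dropped, which would
#' inflate every reported metric.
#'
#' @param predictions character (or integer) vector of predicted labels in
#'   `{"0", "1", "ND"}`.
#' @param truth vector of true labels in `{0, 1}`.
#' @return An object of class `confusion`: list with `TP`, `TN`, `FP`,
#'   `FN`.
#' @export
confusion <- function(predictions, truth) {
  if (length(predictions) != length(truth))
    stop("`predictions` and `truth` must have equal length", call. = FALSE)
  p <- as.character(predictions)
  t <- as.integer(as.character(truth))
  structure(list(
    TP = sum(p == "1" & t == 1L),
    TN = sum(p == "0" & t == 0L),
    FP = sum((p == "1" | p == "ND") & t == 0L),
    FN = sum((p == "0" | p == "ND") & t == 1L)),
    class = "confusion")
}

#' @export
print.confusion <- function(x, ...) {
  cat(sprintf("TP=%d TN=%d FP=%d FN=%d\n", x$TP, x$TN, x$FP, x$FN))
  invisible(x)
}

#' Screening efficiency metrics
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)` and precision `TP/(TP+FP)`. A metric with a zero
#' denominator is reported as `NA` (undefined), never silently as 0; the
#' `undefined` attribute names the affected metrics.
#'
#' @param c a [confusion] object.
#' @return Named numeric vector `ACC`, `SENS`, `SPEC`, `PREC` with an
#'   `undefined` attribute.
#' @export
classification_metrics <- function(c) {
  rat <- function(num, den) if (den == 0) NA_real_ else num / den
  out <- c(ACC = rat(c$TP + c$TN, c$TP + c$TN + c$FP + c$FN),
           SENS = rat(c$TP, c$TP + c$FN),
           SPEC = rat(c$TN, c$TN + c$FP),
           PREC = rat(c$TP, c$TP + c$FP))
  attr(out, "undefined") <- names(out)[is.na(out)]
  out
}

#' Federated plurality vote with entropy tie-break
#'
#' Combines per-client predictions for the same evaluation objects into a
#' federated decision: plurality over the labels `{0, 1}` (abstentions do
#' not vote); on a tied vote the winning label is the one whose supporting
#' clients contain the minimal representative entropy under `order`
#' (residual ties: smaller entropy midpoint, then smaller client index);
#' when every client abstains the federated decision abstains too.
#'
#' @param per_client list of per-client prediction data frames as returned
#'   by [predict.iv_knn()], all over the same evaluation objects.
#' @param order an [order_spec] for the entropy tie-break.
#' @return A character vector of federated labels.
#' @export
federated_vote <- function(per_client, order = order_spec("admissible")) {
  if (!length(per_client)) stop("no client predictions supplied", call. = FALSE)
  n <- nrow(per_client[[1L]])
  m <- length(per_client)
  labels <- vapply(per_client, function(p) p$label, character(n))
  if (n == 1L) labels <- matrix(labels, nrow = 1L)
  out <- character(n)
  for (i in seq_len(n)) {
    v <- labels[i, ]
    n1 <- sum(v == "1"); n0 <- sum(v == "0")
    if (n1 == 0L && n0 == 0L) { out[i] <- "ND"; next }
    if (n1 != n0) { out[i] <- if (n1 > n0) "1" else "0"; next }
    # tie: minimal representative entropy among the supporting clients
    best <- NULL
    for (ci in seq_len(m)) {
      lab <- v[ci]
      if (!(lab %in% c("0", "1"))) next
      p <- per_client[[ci]]
      el <- if (lab == "1") p$e1_lo[i] else p$e0_lo[i]
      eh <- if (lab == "1") p$e1_hi[i] else p$e0_hi[i]
      if (is.na(el)) next
      cand <- list(label = lab, e = iv(el, eh), client = ci)
      if (is.null(best)) { best <- cand; next }
      cmp <- iv_compare(cand$e, best$e, order)
      better <- cmp == "less" ||
        (cmp %in% c("equal", "incomparable") &&
           (iv_mid(cand$e) < iv_mid(best$e) - order$tol))
      if (better) best <- cand
    }
    out[i] <- if (is.null(best)) "ND" else best$label
  }
  out
}

#' Efficiency-gated decision rule
#'
#' Clients whose local efficiency (the gating metric, measured on the
#' shared evaluation set) is strictly lower than the federation's adopt
#' the federated decisions; the others keep their local decisions. By
#' construction the post-rule gating metric of every client equals
#' `max(local, federated)` on that evaluation set — federation never
#' worsens a client.
#'
#' @param ef_name gating metric: `"ACC"`, `"SENS"`, `"SPEC"` or `"PREC"`.
#' @param local_efs numeric vector: per-client gating metric values.
#' @param federated_ef the federation's gating metric value.
#' @param local_preds list of per-client label vectors.
#' @param federated_preds federated label vector.
#' @param truth true labels (used to recompute post-rule metrics).
#' @return A list with `adopted` (logical per client), `final` (list of
#'   per-client final label vectors) and `metrics` (per-client post-rule
#'   metric rows).
#' @export
decision_rule <- function(ef_name = c("ACC", "SENS", "SPEC", "PREC"),
                          local_efs, federated_ef, local_preds,
                          federated_preds, truth) {
  ef_name <- match.arg(ef_name)
  adopted <- !is.na(local_efs) & !is.na(federated_ef) & local_efs < federated_ef
  final <- lapply(seq_along(local_preds), function(ci)
    if (adopted[ci]) federated_preds else local_preds[[ci]])
  metrics <- do.call(rbind, lapply(final, function(lbl)
    classification_metrics(confusion(lbl, truth))))
  list(adopted = adopted, final = final,
       metrics = as.data.frame(metrics))
}

# fit per-client models, evaluate all on the shared test set
eval_clients <- function(clients, test, config) {
  lapply(clients, function(cl) {
    fit <- iv_knn(cl, config)
    predict(fit, test)
  })
}

#' Run an experimental scenario
#'
#' Reproduces the three evaluation designs on a record data frame:
#' \describe{
#'   \item{`s1`}{centralized model: stratified 70/30 holdout, one
#'     classifier trained on the training part;}
#'   \item{`s2`}{local models: NON-IID three-client split with a balanced
#'     15% test pool; each client's model is evaluated on the shared
#'     pool;}
#'   \item{`s3`}{federated decision-making: `s2` plus the federated
#'     plurality vote and the efficiency-gated decision rule (gating
#'     metric `ef`, default accuracy).}
#' }
#' Each repetition redraws the split with a seed derived from `seed`;
#' metric rows are reported per repetition together with their
#' mean/sd summary.
#'
#' @param scenario `"s1"`, `"s2"` or `"s3"`.
#' @param data a record data frame; defaults to the synthetic profile
#'   (`generate_synthetic(seed = seed)`).
#' @param config a [classifier_config].
#' @param repetitions number of independent resampled splits.
#' @param seed master seed for data generation (when `data` is `NULL`) and
#'   splitting.
#' @param ef gating metric for the decision rule in `s3`.
#' @return An object of class `scenario_run`: list with `scenario`,
#'   `metrics` (a long data frame with columns `rep`, `unit`, `ACC`,
#'   `SENS`, `SPEC`, `PREC`) and `summary` (mean and sd per unit).
#' @export
run_scenario <- function(scenario = c("s1", "s2", "s3"), data = NULL,
                         config = classifier_config(), repetitions = 10,
                         seed = 1, ef = "ACC") {
  scenario <- match.arg(scenario)
  stopifnot(repetitions >= 1)
  if (is.null(data)) data <- generate_synthetic(seed = seed)
  seeds <- derive_seeds(seed, repetitions)
  rows <- list()
  for (r in seq_len(repetitions)) {
    if (scenario == "s1") {
      sp <- split_records(data, split_plan("holdout_70_30", seed = seeds[r]))
      fit <- iv_knn(sp$train, config)
      pred <- predict(fit, sp$test)
      met <- classification_metrics(confusion(pred$label, sp$test$dec))
      rows[[length(rows) + 1L]] <-
        data.frame(rep = r, unit = "central", t(met))
    } else {
      sp <- split_records(data, split_plan("noniid_3clients", seed = seeds[r]))
      preds <- eval_clients(sp$clients, sp$test, config)
      truth <- sp$test$dec
      local_met <- lapply(preds, function(p)
        classification_metrics(confusion(p$label, truth)))
      for (ci in seq_along(preds))
        rows[[length(rows) + 1L]] <-
          data.frame(rep = r, unit = paste0("client", ci), t(local_met[[ci]]))
      if (scenario == "s3") {
        fd <- federated_vote(preds, config$order)
        fed_met <- classification_metrics(confusion(fd, truth))
        rows[[length(rows) + 1L]] <-
          data.frame(rep = r, unit = "federated", t(fed_met))
        dr <- decision_rule(ef,
                            vapply(local_met, function(m) m[[ef]], 0),
                            fed_met[[ef]],
                            lapply(preds, function(p) p$label),
                            fd, truth)
        for (ci in seq_along(preds))
          rows[[length(rows) + 1L]] <-
            data.frame(rep = r, unit = paste0("postrule_client", ci),
                       dr$metrics[ci, , drop = FALSE])
      }
    }
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  agg <- stats::aggregate(metrics[c("ACC", "SENS", "SPEC", "PREC")],
                          by = list(unit = metrics$unit),
                          function(x) c(mean = mean(x, na.rm = TRUE),
                                        sd = stats::sd(x)))
  structure(list(scenario = scenario, metrics = metrics, summary = agg,
                 repetitions = repetitions, seed = seed, ef = ef),
            class = "scenario_run")
}

#' @export
print.scenario_run <- function(x, ...) {
  cat(sprintf("<scenario_run %s: %d repetition(s), gate = %s>\n",
              x$scenario, x$repetitions, x$ef))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-18s ACC %.3f  SENS %.3f  SPEC %.3f  PREC %.3f\n",
                s$unit[i], s$ACC[i, "mean"], s$SENS[i, "mean"],
                s$SPEC[i, "mean"], s$PREC[i, "mean"]))
  }
  invisible(x)
}
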