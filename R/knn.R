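#' Classifier configuration
#'
#' Bundles every tunable of the interval kNN classifier: the neighbourhood
#' size `k`, the comparison regime used for ranking similarities, comparing
#' entropies and deciding between class evidence intervals, the similarity
#' and entropy measure families, the condition-attribute set, and the
#' neighbour-selection strategy.
#'
#' `neighbor_strategy = "per_class_k"` ranks each decision class's
#' training objects by similarity to the query, takes the top `k` per
#' class, and picks the minimum-entropy member as that class's
#' representative. `"global_k"` takes the top `k` over the whole training
#' set and then picks the minimum-entropy member per class present among
#' them. Ranking under a partial regime extracts maximal elements
#' iteratively; ties are broken by smaller similarity width, then smaller
#' record id.
#'
#' @param k neighbourhood size (default 5).
#' @param order an [order_spec] (default: the admissible midpoint/upper
#'   lexicographic order).
#' @param similarity a [similarity_spec] (default: possible family).
#' @param entropy an [entropy_spec] (default: possible family).
#' @param condition_attributes attribute indices used for similarity and
#'   entropy; must exclude the verification attributes.
#' @param verification_attributes the two reverse-scored verification
#'   items consulted by [verify_decision()].
#' @param neighbor_strategy `"per_class_k"` or `"global_k"`.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(k = 5,
                              order = order_spec("admissible"),
                              similarity = similarity_spec("possible"),
                              entropy = entropy_spec("possible"),
                              condition_attributes = 1:20,
                              verification_attributes = 21:22,
                              neighbor_strategy = c("per_class_k", "global_k")) {
  neighbor_strategy <- match.arg(neighbor_strategy)
  stopifnot(k >= 1, inherits(order, "order_spec"),
            inherits(similarity, "similarity_spec"),
            inherits(entropy, "entropy_spec"))
  if (length(intersect(condition_attributes, verification_attributes)))
    stop("condition attributes must exclude the verification attributes",
         call. = FALSE)
  structure(list(k = as.integer(k), order = order, similarity = similarity,
                 entropy = entropy,
                 condition_attributes = condition_attributes,
                 verification_attributes = verification_attributes,
                 neighbor_strategy = neighbor_strategy),
            class = "classifier_config")
}

#' Similarity between two fuzzified records
#'
#' The interval similarity of the two records' condition-attribute IVFSs
#' under the configured similarity measure.
#'
#' @param y,x [iv] vectors of fuzzified answers with identical layout.
#' @param config a [classifier_config].
#' @return A single interval ([iv] of length 1).
#' @export
object_similarity <- function(y, x, config = classifier_config()) {
  ca <- config$condition_attributes
  iv_similarity(y[ca], x[ca], config$similarity)
}

# strictly-greater matrix under an order: G[i, j] <=> interval i > interval j
strict_gt_matrix <- function(lo, hi, order) {
  n <- length(lo)
  I <- rep(seq_len(n), times = n)   # row index
  J <- rep(seq_len(n), each = n)    # column index
  lij <- leq_lohi(lo[I], hi[I], lo[J], hi[J], order)  # leq(i, j)
  L <- matrix(lij, n, n)
  t(L) & !L
}

# iterative top-k extraction: repeatedly take the maximal elements under
# `order`, break ties by smaller width then smaller id
select_top_k <- function(lo, hi, ids, k, order) {
  n <- length(lo)
  G <- strict_gt_matrix(lo, hi, order)
  w <- hi - lo
  remaining <- seq_len(n)
  sel <- integer(0)
  while (length(sel) < k && length(remaining)) {
    dominated <- colSums(G[remaining, remaining, drop = FALSE]) > 0
    maximal <- remaining[!dominated]
    pick <- maximal[order(w[maximal], ids[maximal])][1L]
    sel <- c(sel, pick)
    remaining <- remaining[remaining != pick]
  }
  sel
}

# minimal-entropy pick among candidate indices; ties by smaller entropy
# width then smaller id
select_min_entropy <- function(elo, ehi, ids, order) {
  G <- strict_gt_matrix(elo, ehi, order)   # G[i,j]: e_i > e_j
  dominated <- rowSums(G) > 0              # i strictly greater than someone
  minimal <- which(!dominated)
  if (!length(minimal)) minimal <- seq_along(elo)
  w <- ehi - elo
  minimal[order(w[minimal], ids[minimal])][1L]
}

# similarity of one query record to every training record (vectorized)
query_similarities <- function(fz_train, qlo, qhi, config) {
  ca <- config$condition_attributes
  n <- fz_train$n
  A <- matrix(qlo[ca], n, length(ca), byrow = TRUE)
  Ah <- matrix(qhi[ca], n, length(ca), byrow = TRUE)
  sim_rows(A, Ah, fz_train$lo[, ca, drop = FALSE],
           fz_train$hi[, ca, drop = FALSE], config$similarity)
}

#' Fit an interval kNN screening classifier
#'
#' Fuzzifies the training records and precomputes each record's object
#' entropy; prediction ranks training records by interval similarity to
#' the query, selects per-class representatives with minimal entropy
#' (lowest uncertainty), decides between the class evidence intervals
#' `d0`/`d1`, and finally applies the verification-question override.
#'
#' @param train a record data frame (see [read_records()],
#'   [generate_synthetic()]).
#' @param config a [classifier_config].
#' @return An object of class `iv_knn`.
#' @examples
#' df <- generate_synthetic(n = 60, seed = 3)
#' fit <- iv_knn(df[1:50, ], classifier_config(k = 3))
#' predict(fit, df[51:60, ])[, c("id", "label")]
#' @export
iv_knn <- function(train, config = classifier_config()) {
  if (nrow(train) == 0L) stop("training set is empty", call. = FALSE)
  fz <- fuzzify(train)
  ca <- config$condition_attributes
  ent <- ent_rows(fz$lo[, ca, drop = FALSE], fz$hi[, ca, drop = FALSE],
                  config$entropy)
  structure(list(fz = fz, entropy_lo = ent$lo, entropy_hi = ent$hi,
                 config = config),
            class = "iv_knn")
}

#' @export
print.iv_knn <- function(x, ...) {
  cat(sprintf("<iv_knn: %d training records, k = %d, %s similarity, %s order>\n",
              x$fz$n, x$config$k, x$config$similarity$family,
              x$config$order$kind))
  invisible(x)
}

# per-class representatives for one query; returns a list keyed "0"/"1"
nearest_by_class_idx <- function(model, qlo, qhi) {
  config <- model$config
  fz <- model$fz
  s <- query_similarities(fz, qlo, qhi, config)
  classes <- sort(unique(fz$dec))
  reps <- list()
  if (config$neighbor_strategy == "per_class_k") {
    for (cl in classes) {
      cand <- which(fz$dec == cl)
      top <- cand[select_top_k(s$lo[cand], s$hi[cand], fz$id[cand],
                               config$k, config$order)]
      best <- top[select_min_entropy(model$entropy_lo[top],
                                     model$entropy_hi[top],
                                     fz$id[top], config$order)]
      reps[[as.character(cl)]] <- list(index = best,
        similarity = new_iv(s$lo[best], s$hi[best]),
        entropy = new_iv(model$entropy_lo[best], model$entropy_hi[best]))
    }
  } else {
    top <- select_top_k(s$lo, s$hi, fz$id, config$k, config$order)
    for (cl in intersect(classes, fz$dec[top])) {
      sub <- top[fz$dec[top] == cl]
      best <- sub[select_min_entropy(model$entropy_lo[sub],
                                     model$entropy_hi[sub],
                                     fz$id[sub], config$order)]
      reps[[as.character(cl)]] <- list(index = best,
        similarity = new_iv(s$lo[best], s$hi[best]),
        entropy = new_iv(model$entropy_lo[best], model$entropy_hi[best]))
    }
  }
  reps
}

#' Per-class nearest representatives
#'
#' Exposes the neighbour-selection stage: for each decision class, the
#' training record whose similarity to the query ranks in the top `k` for
#' that class and whose object entropy is minimal among those.
#'
#' @param y an [iv] vector: the fuzzified query record.
#' @param model an [iv_knn] fit.
#' @return A list keyed by class label; each element holds `index` (row in
#'   the training set), `similarity` and `entropy` intervals.
#' @export
nearest_by_class <- function(y, model) {
  stopifnot(inherits(model, "iv_knn"), inherits(y, "iv"))
  nearest_by_class_idx(model, iv_lo(y), iv_hi(y))
}

#' Decide between the class evidence intervals
#'
#' Implements the decision cascade on the per-class evidence intervals
#' `d0` (no depression) and `d1` (depression risk): (i) a single present
#' class wins; (ii) a strict order relation between `d1` and `d0` under
#' the configured regime decides; (iii) otherwise each is compared to the
#' neutral interval `[0.5, 0.5]` and the unique class at-or-above neutral
#' while the other is below wins; (iv) otherwise the narrower evidence
#' interval wins; (v) otherwise the classifier abstains (`"ND"`).
#'
#' @param d0,d1 evidence intervals ([iv] of length 1) or `NULL` when the
#'   class is absent from the training neighbourhood.
#' @param config a [classifier_config].
#' @return A list with `label` (`"0"`, `"1"` or `"ND"`) and `rule` (which
#'   cascade step decided).
#' @export
classify_intervals <- function(d0, d1, config = classifier_config()) {
  if (is.null(d0) && is.null(d1))
    stop("at least one of `d0`, `d1` must be present", call. = FALSE)
  if (is.null(d1)) return(list(label = "0", rule = "only_class"))
  if (is.null(d0)) return(list(label = "1", rule = "only_class"))
  ord <- config$order
  cmp <- iv_compare(d1, d0, ord)
  if (cmp == "greater") return(list(label = "1", rule = "order"))
  if (cmp == "less") return(list(label = "0", rule = "order"))
  neutral <- iv(0.5, 0.5)
  ge1 <- iv_leq(neutral, d1, ord); lt1 <- iv_compare(d1, neutral, ord) == "less"
  ge0 <- iv_leq(neutral, d0, ord); lt0 <- iv_compare(d0, neutral, ord) == "less"
  win1 <- ge1 && lt0
  win0 <- ge0 && lt1
  if (win1 && !win0) return(list(label = "1", rule = "neutral"))
  if (win0 && !win1) return(list(label = "0", rule = "neutral"))
  w1 <- iv_width(d1); w0 <- iv_width(d0)
  if (w1 < w0 - ord$tol) return(list(label = "1", rule = "width"))
  if (w0 < w1 - ord$tol) return(list(label = "0", rule = "width"))
  list(label = "ND", rule = "no_decision")
}

#' Verification-question override
#'
#' The two reverse-scored verification items (attributes 21–22) guard
#' against missed risk: when the primary outcome is "no depression" or an
#' abstention and either verification answer is a definite value below 2
#' on the 0–4 scale (fuzzified: a degenerate interval below 0.5), the
#' outcome is overridden to the risk class. Missing verification answers
#' (`[0, 1]`) never trigger, and a risk label is never changed.
#'
#' @param record an [iv] vector of the query's 22 fuzzified answers.
#' @param prediction a prediction list with at least `label`.
#' @param config a [classifier_config] (identifies the verification
#'   attributes).
#' @return The prediction with `label` possibly overridden and
#'   `verification_fired` set.
#' @export
verify_decision <- function(record, prediction, config = classifier_config()) {
  va <- config$verification_attributes
  lo <- iv_lo(record)[va]; hi <- iv_hi(record)[va]
  trigger <- any(hi - lo <= 1e-12 & lo < 0.5)
  prediction$verification_fired <- FALSE
  if (prediction$label %in% c("0", "ND") && trigger) {
    prediction$label <- "1"
    prediction$verification_fired <- TRUE
  }
  prediction
}

# full pipeline for one fuzzified query (endpoint vectors of length 22)
predict_one <- function(model, qlo, qhi) {
  reps <- nearest_by_class_idx(model, qlo, qhi)
  d0 <- if (!is.null(reps[["0"]])) reps[["0"]]$similarity
  d1 <- if (!is.null(reps[["1"]])) reps[["1"]]$similarity
  pred <- classify_intervals(d0, d1, model$config)
  pred$d0 <- d0; pred$d1 <- d1
  pred$e0 <- if (!is.null(reps[["0"]])) reps[["0"]]$entropy
  pred$e1 <- if (!is.null(reps[["1"]])) reps[["1"]]$entropy
  verify_decision(new_iv(qlo, qhi), pred, model$config)
}

#' Predict screening outcomes
#'
#' @param object an [iv_knn] fit.
#' @param newdata a record data frame of queries.
#' @param ... unused.
#' @return A data frame with one row per query: `id`, `label` (`"0"`,
#'   `"1"` or `"ND"`), the evidence interval endpoints `d0_lo`, `d0_hi`,
#'   `d1_lo`, `d1_hi`, the representative entropies `e0_lo`..`e1_hi`
#'   (`NA` when the class is absent), the deciding `rule`, and
#'   `verification_fired`.
#' @export
predict.iv_knn <- function(object, newdata, ...) {
  fq <- fuzzify(newdata)
  n <- fq$n
  out <- data.frame(id = fq$id, label = character(n),
                    d0_lo = NA_real_, d0_hi = NA_real_,
                    d1_lo = NA_real_, d1_hi = NA_real_,
                    e0_lo = NA_real_, e0_hi = NA_real_,
                    e1_lo = NA_real_, e1_hi = NA_real_,
                    rule = character(n), verification_fired = logical(n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    p <- predict_one(object, fq$lo[i, ], fq$hi[i, ])
    out$label[i] <- p$label
    out$rule[i] <- p$rule
    out$verification_fired[i] <- p$verification_fired
    if (!is.null(p$d0)) { out$d0_lo[i] <- iv_lo(p$d0); out$d0_hi[i] <- iv_hi(p$d0) }
    if (!is.null(p$d1)) { out$d1_lo[i] <- iv_lo(p$d1); out$d1_hi[i] <- iv_hi(p$d1) }
    if (!is.null(p$e0)) { out$e0_lo[i] <- iv_lo(p$e0); out$e0_hi[i] <- iv_hi(p$e0) }
    if (!is.null(p$e1)) { out$e1_lo[i] <- iv_lo(p$e1); out$e1_hi[i] <- iv_hi(p$e1) }
  }
  out
}
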