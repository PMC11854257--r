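#' Read and write screening-questionnaire records
#'
#' Records follow the layout of a 22-item screening questionnaire: answer
#' columns `q1`..`q22` on the 0–4 Likert scale (blank or `NA` cells denote
#' missing answers) and a binary decision column `dec` (0 = no depression,
#' 1 = depression risk) that is never missing. Attributes 1–20 are basic
#' risk items ("the more, the worse"); attributes 21–22 are reverse-scored
#' verification items ("the more, the better"). Orientation is metadata:
#' answers are stored as given, never rescaled.
#'
#' @param path path to a CSV file with header `q1,...,q22,dec`.
#' @return A data frame with integer columns `q1`..`q22` (may contain
#'   `NA`), `dec`, and an `id` column preserving row order.
#' @export
read_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"), colClasses = "character")
  validate_records(df, origin = path)
}

#' @param records a record data frame as returned by [read_records()] or
#'   [generate_synthetic()].
#' @rdname read_records
#' @export
write_records <- function(records, path) {
  out <- records[c(paste0("q", 1:22), "dec")]
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

# validate and coerce a raw answers table into the canonical record frame
validate_records <- function(df, origin = "records") {
  need <- c(paste0("q", 1:22), "dec")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop(origin, ": missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  df <- df[need]
  for (j in paste0("q", 1:22)) {
    raw <- df[[j]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- !is.na(raw) & (is.na(val) | val != round(val) | val < 0 | val > 4)
    if (any(bad))
      stop(sprintf("%s: answer out of range in column %s, row %d (value %s)",
                   origin, j, which(bad)[1L], raw[which(bad)[1L]]),
           call. = FALSE)
    df[[j]] <- as.integer(val)
  }
  dval <- suppressWarnings(as.numeric(df$dec))
  if (anyNA(dval))
    stop(origin, ": missing decision in row ",
         which(is.na(dval))[1L], call. = FALSE)
  if (any(dval != round(dval) | !(dval %in% c(0, 1))))
    stop(origin, ": decision must be 0 or 1 (row ",
         which(!(dval %in% c(0, 1)))[1L], ")", call. = FALSE)
  df$dec <- as.integer(dval)
  df$id <- seq_len(nrow(df))
  df
}

#' Fuzzify questionnaire records into interval-valued form
#'
#' The two-stage fuzzification: (stage 1) each answered value `a` on the
#' 0–4 scale is normalized to `b = a/4`; (stage 2) `b` is embedded as the
#' degenerate interval `[b, b]`, while a missing answer becomes the whole
#' unit interval `[0, 1]` — the epistemic "anything is possible" value.
#' Decisions are copied unchanged.
#'
#' @param records a record data frame (see [read_records()]).
#' @return An object of class `fuzzy_records`: a list with numeric
#'   matrices `lo` and `hi` (rows = records, 22 columns), integer vectors
#'   `dec` and `id`, and `n`.
#' @examples
#' df <- generate_synthetic(n = 10, seed = 1)
#' fz <- fuzzify(df)
#' fz$lo[1, 1:5]
#' @export
fuzzify <- function(records) {
  qcols <- paste0("q", 1:22)
  a <- as.matrix(records[qcols])
  storage.mode(a) <- "double"
  b <- a / 4
  lo <- ifelse(is.na(b), 0, b)
  hi <- ifelse(is.na(b), 1, b)
  dimnames(lo) <- dimnames(hi) <- NULL
  structure(list(lo = lo, hi = hi, dec = as.integer(records$dec),
                 id = if (!is.null(records$id)) as.integer(records$id)
                      else seq_len(nrow(records)),
                 n = nrow(records)),
            class = "fuzzy_records")
}

#' @export
print.fuzzy_records <- function(x, ...) {
  cat(sprintf("<fuzzy_records: %d records, 22 attributes, %d positive>\n",
              x$n, sum(x$dec == 1L)))
  invisible(x)
}

# extract record i of a fuzzy_records object as an iv vector of length 22
fuzzy_record_iv <- function(fz, i) new_iv(fz$lo[i, ], fz$hi[i, ])

# subset a fuzzy_records object by record index
fuzzy_subset <- function(fz, idx) {
  structure(list(lo = fz$lo[idx, , drop = FALSE],
                 hi = fz$hi[idx, , drop = FALSE],
                 dec = fz$dec[idx], id = fz$id[idx], n = length(idx)),
            class = "fuzzy_records")
}

#' Generate synthetic screening-questionnaire records
#'
#' Emulates the profile of a depression-screening survey: by default 750
#' records with exactly 249 positive decisions and about 5% of answer
#' cells missing. A latent-severity model drives the answers: each subject
#' draws a severity \eqn{s \sim N(0, 1)} (class 0) or
#' \eqn{s \sim N(\mathrm{effect\_size}, 1)} (class 1); the 20 risk items
#' are noisy monotone-increasing discretizations of `s` onto `{0,...,4}`
#' and the 2 verification items are monotone-decreasing in `s` (reverse
#' scored). Class counts are fixed exactly (not Bernoulli draws) so the
#' fixture profile is deterministic; each answer cell is masked missing
#' independently with probability `missing_rate`.
#'
#' @param n number of records.
#' @param positive_fraction fraction of decision-1 records; the positive
#'   count is `round(n * positive_fraction)`.
#' @param missing_rate per-cell probability of a missing answer.
#' @param effect_size upward shift, in latent standard deviations, of the
#'   class-1 severity distribution.
#' @param seed integer seed; the same seed reproduces the output exactly.
#' @return A record data frame (columns `q1`..`q22`, `dec`, `id`).
#' @examples
#' df <- generate_synthetic(n = 20, positive_fraction = 0.5,
#'                          missing_rate = 0, seed = 7)
#' table(df$dec)
#' @export
generate_synthetic <- function(n = 750, positive_fraction = 249 / 750,
                               missing_rate = 0.05, effect_size = 2,
                               seed = NULL) {
  if (n < 1) stop("`n` must be at least 1", call. = FALSE)
  if (positive_fraction < 0 || positive_fraction > 1)
    stop("`positive_fraction` must lie in [0, 1]", call. = FALSE)
  if (missing_rate < 0 || missing_rate > 1)
    stop("`missing_rate` must lie in [0, 1]", call. = FALSE)
  with_seed(seed, {
    n1 <- round(n * positive_fraction)
    dec <- integer(n)
    dec[sample.int(n, n1)] <- 1L
    s <- stats::rnorm(n, mean = ifelse(dec == 1L, effect_size, 0), sd = 1)
    clamp04 <- function(x) pmin(pmax(round(x), 0), 4)
    ans <- matrix(0L, n, 22)
    for (j in 1:20)
      ans[, j] <- clamp04(1 + s + stats::rnorm(n, 0, 0.75))
    for (j in 21:22)
      ans[, j] <- clamp04(3 - s + stats::rnorm(n, 0, 0.75))
    if (missing_rate > 0)
      ans[matrix(stats::runif(n * 22) < missing_rate, n, 22)] <- NA_integer_
    df <- as.data.frame(ans)
    names(df) <- paste0("q", 1:22)
    df$dec <- dec
    df$id <- seq_len(n)
    df
  })
}

#' Dataset split plans for the experimental scenarios
#'
#' Three splitters cover the evaluation designs:
#' \describe{
#'   \item{`holdout_70_30`}{stratified 70% train / 30% test;}
#'   \item{`noniid_3clients`}{a class-balanced test pool (default 15% of
#'     the data, half per class) is removed first; the remainder is split
#'     into three equally sized, disjoint clients with NON-IID class
#'     mixes — client 1 balanced 50/50, client 2 with 80% class 0,
#'     client 3 with 80% class 1. The common client size is the largest
#'     feasible given the available per-class counts; when the source
#'     data are imbalanced some records necessarily remain unused and are
#'     returned as `unused`;}
#'   \item{`kfold_10`}{stratified k folds (default 10).}
#' }
#'
#' @param scenario one of `"holdout_70_30"`, `"noniid_3clients"`,
#'   `"kfold_10"`.
#' @param test_fraction test share: 0.3 for the holdout plan, 0.15 for the
#'   balanced NON-IID test pool.
#' @param client_positive_mix per-client fractions of class-1 records for
#'   the NON-IID plan.
#' @param folds number of folds for `kfold_10`.
#' @param seed integer seed used by [split_records()].
#' @return An object of class `split_plan`.
#' @export
split_plan <- function(scenario = c("holdout_70_30", "noniid_3clients", "kfold_10"),
                       test_fraction = NULL,
                       client_positive_mix = c(0.5, 0.2, 0.8),
                       folds = 10, seed = 1) {
  scenario <- match.arg(scenario)
  if (is.null(test_fraction))
    test_fraction <- if (scenario == "holdout_70_30") 0.3 else 0.15
  stopifnot(test_fraction > 0, test_fraction < 1, folds >= 2,
            all(client_positive_mix >= 0 & client_positive_mix <= 1))
  structure(list(scenario = scenario, test_fraction = test_fraction,
                 client_positive_mix = client_positive_mix,
                 folds = folds, seed = seed),
            class = "split_plan")
}

#' Split records according to a plan
#'
#' @param records a record data frame.
#' @param plan a [split_plan].
#' @return For `holdout_70_30`: `list(train, test)`. For
#'   `noniid_3clients`: `list(test, clients, unused)` where `clients` is a
#'   list of three record data frames. For `kfold_10`: a list of `folds`
#'   index vectors over `records`.
#' @export
split_records <- function(records, plan) {
  stopifnot(inherits(plan, "split_plan"))
  idx0 <- which(records$dec == 0L)
  idx1 <- which(records$dec == 1L)
  with_seed(plan$seed, {
    switch(plan$scenario,
      holdout_70_30 = {
        tr0 <- sample(idx0, round(length(idx0) * (1 - plan$test_fraction)))
        tr1 <- sample(idx1, round(length(idx1) * (1 - plan$test_fraction)))
        train <- sort(c(tr0, tr1))
        list(train = records[train, , drop = FALSE],
             test = records[-train, , drop = FALSE])
      },
      noniid_3clients = {
        per_class <- round(nrow(records) * plan$test_fraction / 2)
        if (length(idx0) < per_class || length(idx1) < per_class)
          stop(sprintf(
            "infeasible test pool: need %d records per class, have %d/%d",
            per_class, length(idx0), length(idx1)), call. = FALSE)
        t0 <- sample(idx0, per_class); t1 <- sample(idx1, per_class)
        pool0 <- sample(setdiff(idx0, t0))
        pool1 <- sample(setdiff(idx1, t1))
        mix <- plan$client_positive_mix
        # largest common client size m with round(m*mix) class-1 demand met
        m <- floor(min(length(pool0) / sum(1 - mix),
                       length(pool1) / sum(mix),
                       (length(pool0) + length(pool1)) / length(mix)))
        need1 <- round(m * mix); need0 <- m - need1
        while (m > 0 && (sum(need1) > length(pool1) || sum(need0) > length(pool0))) {
          m <- m - 1
          need1 <- round(m * mix); need0 <- m - need1
        }
        if (m < 2)
          stop(sprintf(
            "infeasible client skew: class mixes %s need more records than the %d/%d available",
            paste(mix, collapse = "/"), length(pool0), length(pool1)),
            call. = FALSE)
        clients <- vector("list", length(mix))
        draw <- function(pool, k) {
          if (k == 0L) return(list(take = integer(0), rest = pool))
          list(take = pool[seq_len(k)], rest = pool[-seq_len(k)])
        }
        for (ci in seq_along(mix)) {
          d1 <- draw(pool1, need1[ci]); pool1 <- d1$rest
          d0 <- draw(pool0, need0[ci]); pool0 <- d0$rest
          clients[[ci]] <- records[sort(c(d0$take, d1$take)), , drop = FALSE]
        }
        list(test = records[sort(c(t0, t1)), , drop = FALSE],
             clients = clients,
             unused = records[sort(c(pool0, pool1)), , drop = FALSE])
      },
      kfold_10 = {
        f0 <- rep_len(seq_len(plan$folds), length(idx0))
        f1 <- rep_len(seq_len(plan$folds), length(idx1))
        assign0 <- split(sample(idx0), f0)
        assign1 <- split(sample(idx1), f1)
        lapply(seq_len(plan$folds),
               function(k) sort(c(assign0[[k]], assign1[[k]])))
      })
  })
}
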