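# Scalar reference implementations, written as direct transcriptions of the
# printed definitions (plain loops and if-chains, no shared code with the
# package internals). Intervals are numeric c(lo, hi); IVFSs are n x 2
# matrices. Used as the independent route in dual-route checks.

o_tol <- 1e-12

o_leq <- function(a, b, kind) {
  switch(kind,
    partial2  = a[1] <= b[1] && a[2] <= b[2],
    possible  = a[1] <= b[2],
    necessary = a[2] <= b[1],
    admissible = {
      pa <- (a[1] + a[2]) / 2; pb <- (b[1] + b[2]) / 2
      if (abs(pa - pb) <= o_tol) a[2] <= b[2] + o_tol else pa < pb
    })
}

o_compare <- function(a, b, kind) {
  eq <- max(abs(a - b)) <= o_tol
  ab <- o_leq(a, b, kind); ba <- o_leq(b, a, kind)
  if (eq || (ab && ba)) "equal"
  else if (ab) "less"
  else if (ba) "greater"
  else "incomparable"
}

o_strict_gt <- function(a, b, kind) o_leq(b, a, kind) && !o_leq(a, b, kind)

# precedence with the standard negation and inner mean, per family
o_prec <- function(a, b, family) {
  if (max(abs(a - b)) <= o_tol) return(c(1 - (a[2] - a[1]), 1))
  lt <- switch(family,
    standard  = a[1] <= b[1] && a[2] <= b[2],
    possible  = a[1] <= b[2],
    necessary = a[2] <= b[1])
  if (lt) return(c(1, 1))
  na <- c(1 - a[2], 1 - a[1])
  switch(family,
    standard  = (na + b) / 2,
    possible  = if (all(na == 0) && all(b == 0)) c(0, 0)
                else c((na[1] + b[1]) / 2, 1),
    necessary = c((na[1] + b[1]) / 2, max((na[1] + b[2]) / 2, (na[2] + b[1]) / 2)))
}

# similarity: outer mean of the meet of both precedence directions
o_sim <- function(A, B, family) {
  n <- nrow(A)
  lo <- numeric(n); hi <- numeric(n)
  for (i in seq_len(n)) {
    p <- pmin(o_prec(A[i, ], B[i, ], family), o_prec(B[i, ], A[i, ], family))
    lo[i] <- p[1]; hi[i] <- p[2]
  }
  c(mean(lo), mean(hi))
}

o_entropy <- function(A, family) o_sim(A, cbind(1 - A[, 2], 1 - A[, 1]), family)

# fuzzify one record row (named q1..q22) into a 22 x 2 matrix
o_fuzzify <- function(row) {
  a <- as.numeric(unlist(row[paste0("q", 1:22)]))
  b <- a / 4
  cbind(ifelse(is.na(b), 0, b), ifelse(is.na(b), 1, b))
}

# iterative maximal extraction with width/id tie-breaks
o_top_k <- function(sims, ids, k, kind) {
  remaining <- seq_along(sims)
  sel <- integer(0)
  while (length(sel) < k && length(remaining)) {
    maximal <- Filter(function(j) {
      !any(vapply(remaining, function(i)
        i != j && o_strict_gt(sims[[i]], sims[[j]], kind), TRUE))
    }, remaining)
    w <- vapply(maximal, function(j) sims[[j]][2] - sims[[j]][1], 0)
    pick <- maximal[order(w, ids[maximal])][1]
    sel <- c(sel, pick)
    remaining <- setdiff(remaining, pick)
  }
  sel
}

o_min_entropy <- function(ents, ids, kind) {
  idx <- seq_along(ents)
  minimal <- Filter(function(j) {
    !any(vapply(idx, function(i)
      i != j && o_strict_gt(ents[[j]], ents[[i]], kind), TRUE))
  }, idx)
  if (!length(minimal)) minimal <- idx
  w <- vapply(minimal, function(j) ents[[j]][2] - ents[[j]][1], 0)
  minimal[order(w, ids[minimal])][1]
}

o_classify <- function(d0, d1, kind) {
  if (is.null(d1)) return("0")
  if (is.null(d0)) return("1")
  cmp <- o_compare(d1, d0, kind)
  if (cmp == "greater") return("1")
  if (cmp == "less") return("0")
  neutral <- c(0.5, 0.5)
  ge1 <- o_leq(neutral, d1, kind); lt1 <- o_compare(d1, neutral, kind) == "less"
  ge0 <- o_leq(neutral, d0, kind); lt0 <- o_compare(d0, neutral, kind) == "less"
  if (ge1 && lt0 && !(ge0 && lt1)) return("1")
  if (ge0 && lt1 && !(ge1 && lt0)) return("0")
  w1 <- d1[2] - d1[1]; w0 <- d0[2] - d0[1]
  if (w1 < w0 - o_tol) return("1")
  if (w0 < w1 - o_tol) return("0")
  "ND"
}

o_verify <- function(fz_record, label) {
  for (j in 21:22) {
    lo <- fz_record[j, 1]; hi <- fz_record[j, 2]
    if (hi - lo <= o_tol && lo < 0.5 && label %in% c("0", "ND")) return("1")
  }
  label
}

# full reference pipeline for one query record
o_predict <- function(query_row, train_df, k, kind, family, strategy,
                      cond_attrs = 1:20) {
  fq <- o_fuzzify(query_row)
  n <- nrow(train_df)
  fz <- lapply(seq_len(n), function(i) o_fuzzify(train_df[i, ]))
  sims <- lapply(fz, function(x)
    o_sim(fq[cond_attrs, , drop = FALSE], x[cond_attrs, , drop = FALSE], family))
  ents <- lapply(fz, function(x) o_entropy(x[cond_attrs, , drop = FALSE], family))
  ids <- train_df$id
  reps <- list()
  if (strategy == "per_class_k") {
    for (cl in sort(unique(train_df$dec))) {
      cand <- which(train_df$dec == cl)
      top <- cand[o_top_k(sims[cand], ids[cand], k, kind)]
      best <- top[o_min_entropy(ents[top], ids[top], kind)]
      reps[[as.character(cl)]] <- sims[[best]]
    }
  } else {
    top <- o_top_k(sims, ids, k, kind)
    for (cl in sort(unique(train_df$dec[top]))) {
      sub <- top[train_df$dec[top] == cl]
      best <- sub[o_min_entropy(ents[sub], ids[sub], kind)]
      reps[[as.character(cl)]] <- sims[[best]]
    }
  }
  label <- o_classify(reps[["0"]], reps[["1"]], kind)
  o_verify(fq, label)
}

# random toy record frame for oracle-equivalence checks: answers only on the
# first n_attr condition attributes, the rest held at 4 except the
# verification items which are random (so the override is exercised)
make_toy_records <- function(n, n_attr = 4, missing_rate = 0.15) {
  ans <- matrix(4L, n, 22)
  ans[, seq_len(n_attr)] <- sample(0:4, n * n_attr, replace = TRUE)
  ans[, 21:22] <- sample(0:4, n * 2, replace = TRUE, prob = c(.1, .1, .2, .3, .3))
  mask <- matrix(runif(n * n_attr) < missing_rate, n, n_attr)
  ans[, seq_len(n_attr)][mask] <- NA_integer_
  df <- as.data.frame(ans)
  names(df) <- paste0("q", 1:22)
  df$dec <- sample(0:1, n, replace = TRUE)
  if (all(df$dec == df$dec[1])) df$dec[1] <- 1L - df$dec[1]
  df$id <- seq_len(n)
  df
}
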