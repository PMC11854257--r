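#' Moore (sup) distance between intervals
#'
#' \eqn{D([a_-, a^+], [b_-, b^+]) = \max(|a_- - b_-|, |a^+ - b^+|)}: the
#' endpointwise Chebyshev distance, a metric on \eqn{L^I} with values in
#' `[0, 1]`.
#'
#' @param a,b [iv] vectors (recycled to common length).
#' @return Numeric vector of distances.
#' @examples
#' moore_distance(iv(0.2, 0.5), iv(0.4, 0.9))   # 0.4
#' @export
moore_distance <- function(a, b) {
  n <- max(iv_length(a), iv_length(b))
  pmax(abs(rep_len(iv_lo(a), n) - rep_len(iv_lo(b), n)),
       abs(rep_len(iv_hi(a), n) - rep_len(iv_hi(b), n)))
}

#' Interval-valued precedence indicators
#'
#' A precedence indicator grades, as an interval, the degree to which one
#' interval precedes another. All three families share a three-branch case
#' skeleton that differs only in the strict relation, the negation and the
#' else-branch aggregation:
#' \deqn{Prec(a, b) = [1 - w(a), 1] \textrm{ if } a = b; \quad
#'       [1, 1] \textrm{ if } a < b; \quad
#'       Agg(N(a), b) \textrm{ otherwise,}}
#' where \eqn{w} is the interval width, `<` is the family's strict relation
#' (componentwise for `standard`, possible for `possible`, necessary for
#' `necessary`, each excluding equality), `N` the family's negation and
#' `Agg` the family's order-consistent aggregation (`mean`, `pos`, `nec`
#' respectively). Under the possible family two distinct overlapping
#' intervals saturate at `[1,1]` in both directions — the optimistic
#' reading of epistemic comparability.
#'
#' @param family one of `"standard"`, `"possible"`, `"necessary"`.
#' @param negation a [negation_spec]; defaults to the standard negation for
#'   every family.
#' @param inner scalar inner aggregation used by the possible family's
#'   else-branch `pos` aggregation.
#' @param tol absolute tolerance for the equality branch.
#' @return An object of class `precedence_spec`.
#' @examples
#' iv_precedence(iv(0.2, 0.6), iv(0.2, 0.6))  # equal branch: [0.4, 1]
#' iv_precedence(iv(0.1, 0.3), iv(0.5, 0.9))  # strict branch: [1, 1]
#' @export
precedence_spec <- function(family = c("possible", "standard", "necessary"),
                            negation = NULL,
                            inner = c("mean", "min", "max", "product"),
                            tol = 1e-12) {
  family <- match.arg(family)
  inner <- match.arg(inner)
  if (is.null(negation)) negation <- negation_spec(family)
  stopifnot(inherits(negation, "negation_spec"))
  structure(list(family = family, negation = negation, inner = inner, tol = tol),
            class = "precedence_spec")
}

# vectorized precedence kernel on raw endpoints; shapes follow the inputs
prec_lohi <- function(alo, ahi, blo, bhi, spec) {
  eq <- pmax(abs(alo - blo), abs(ahi - bhi)) <= spec$tol
  lt <- switch(spec$family,
    standard  = alo <= blo & ahi <= bhi,
    possible  = alo <= bhi,
    necessary = ahi <= blo) & !eq
  neg <- spec$negation$map(new_iv(as.vector(alo), as.vector(ahi)))
  nlo <- iv_lo(neg); nhi <- iv_hi(neg)
  els <- switch(spec$family,
    standard  = list(lo = (nlo + as.vector(blo)) / 2, hi = (nhi + as.vector(bhi)) / 2),
    possible  = agg_pos_lohi(nlo, nhi, as.vector(blo), as.vector(bhi), spec$inner),
    necessary = agg_nec_lohi(nlo, nhi, as.vector(blo), as.vector(bhi)))
  list(lo = ifelse(eq, 1 - (ahi - alo), ifelse(lt, 1, els$lo)),
       hi = ifelse(eq | lt, 1, els$hi))
}

#' @param a,b [iv] vectors (recycled to common length).
#' @param spec a `precedence_spec`.
#' @rdname precedence_spec
#' @export
iv_precedence <- function(a, b, spec = precedence_spec()) {
  n <- max(iv_length(a), iv_length(b))
  p <- prec_lohi(rep_len(iv_lo(a), n), rep_len(iv_hi(a), n),
                 rep_len(iv_lo(b), n), rep_len(iv_hi(b), n), spec)
  new_iv(as.vector(p$lo), as.vector(p$hi))
}

#' Interval-valued similarity between IVFSs
#'
#' The similarity of two interval-valued fuzzy sets over a shared finite
#' universe is built from a precedence indicator evaluated in both
#' directions, a binary pairer combining the two directions per universe
#' element (default: the lattice meet \eqn{\wedge}), and an outer
#' aggregation across elements (default: componentwise mean):
#' \deqn{S(A, B) = \mathop{Agg}_{i=1}^{n}\; B(Prec(A(x_i), B(x_i)),
#'       Prec(B(x_i), A(x_i))).}
#' With a commutative pairer the construction is symmetric in `A` and `B`.
#'
#' @param family one of `"standard"`, `"possible"`, `"necessary"`; selects
#'   the matching default precedence indicator.
#' @param outer [aggregation_spec] applied across universe elements.
#' @param pairer [aggregation_spec] combining the two precedence
#'   directions; the default meet is the printed choice.
#' @param precedence a [precedence_spec]; defaults to the family's.
#' @return An object of class `similarity_spec`.
#' @examples
#' A <- iv(c(0.2, 0.5), c(0.6, 0.5))
#' iv_similarity(A, A)   # [0.8, 1]: mean of [1-w(A(x)), 1]
#' @export
similarity_spec <- function(family = c("possible", "standard", "necessary"),
                            outer = aggregation_spec("mean"),
                            pairer = aggregation_spec("meet"),
                            precedence = NULL) {
  family <- match.arg(family)
  if (is.null(precedence)) precedence <- precedence_spec(family)
  stopifnot(inherits(outer, "aggregation_spec"),
            inherits(pairer, "aggregation_spec"),
            inherits(precedence, "precedence_spec"))
  structure(list(family = family, outer = outer, pairer = pairer,
                 precedence = precedence),
            class = "similarity_spec")
}

# combine the two precedence directions elementwise
pair_lohi <- function(l1, h1, l2, h2, pairer) {
  switch(pairer$family,
    meet = list(lo = pmin(l1, l2), hi = pmin(h1, h2)),
    mean = list(lo = (l1 + l2) / 2, hi = (h1 + h2) / 2),
    pos  = agg_pos_lohi(l1, h1, l2, h2, pairer$inner),
    nec  = agg_nec_lohi(l1, h1, l2, h2))
}

# aggregate across the columns of paired lo/hi matrices, one result per row
outer_rows <- function(plo, phi, outer) {
  if (outer$family == "mean") return(list(lo = rowMeans(plo), hi = rowMeans(phi)))
  if (outer$family == "meet") {
    return(list(lo = do.call(pmin, as.data.frame(plo)),
                hi = do.call(pmin, as.data.frame(phi))))
  }
  n <- nrow(plo)
  lo <- numeric(n); hi <- numeric(n)
  for (i in seq_len(n)) {
    r <- iv_aggregate(new_iv(plo[i, ], phi[i, ]), outer)
    lo[i] <- iv_lo(r); hi[i] <- iv_hi(r)
  }
  list(lo = lo, hi = hi)
}

# similarity kernel: A, B given as lo/hi matrices (rows = sets, cols = universe)
sim_rows <- function(alo, ahi, blo, bhi, spec) {
  p1 <- prec_lohi(alo, ahi, blo, bhi, spec$precedence)
  p2 <- prec_lohi(blo, bhi, alo, ahi, spec$precedence)
  pr <- pair_lohi(p1$lo, p1$hi, p2$lo, p2$hi, spec$pairer)
  dim(pr$lo) <- dim(alo); dim(pr$hi) <- dim(alo)
  outer_rows(pr$lo, pr$hi, spec$outer)
}

#' @param A,B [iv] vectors of equal length interpreted as two IVFSs over
#'   the same universe (element `i` of each is the membership of the
#'   `i`-th universe element).
#' @param spec a `similarity_spec`.
#' @rdname similarity_spec
#' @export
iv_similarity <- function(A, B, spec = similarity_spec()) {
  if (iv_length(A) != iv_length(B))
    stop("`A` and `B` must be IVFSs over the same universe", call. = FALSE)
  if (iv_length(A) == 0L) stop("the universe must be non-empty", call. = FALSE)
  s <- sim_rows(matrix(iv_lo(A), nrow = 1L), matrix(iv_hi(A), nrow = 1L),
                matrix(iv_lo(B), nrow = 1L), matrix(iv_hi(B), nrow = 1L), spec)
  new_iv(s$lo, s$hi)
}
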