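#' Intervals of the unit interval
#'
#' Construct elements of \eqn{L^I}, the complete lattice of closed
#' subintervals \eqn{[lo, hi] \subseteq [0,1]}. An `iv` object is a numeric
#' matrix with columns `lo` and `hi`; a single interval is a one-row matrix
#' and a vector of intervals has one row per interval. Read epistemically, an
#' interval brackets a single unknown true membership value; the degenerate
#' interval `[b, b]` carries no uncertainty.
#'
#' @param lo numeric vector of lower endpoints, each in `[0, 1]`.
#' @param hi numeric vector of upper endpoints, each in `[0, 1]` and not
#'   below the corresponding `lo`. Defaults to `lo` (degenerate intervals).
#' @return An object of class `iv`: a numeric matrix with columns
#'   `lo`, `hi`.
#' @examples
#' iv(0.2, 0.7)
#' iv_width(iv(0.2, 0.7))         # 0.5
#' iv(c(0, 0.5), c(1, 0.5))       # two intervals, one degenerate
#' @seealso [iv_leq()], [iv_negate()], [iv_join()], `format()`
#' @export
iv <- function(lo, hi = lo) {
  if (!is.numeric(lo)) stop("`lo` must be numeric", call. = FALSE)
  if (!is.numeric(hi)) stop("`hi` must be numeric", call. = FALSE)
  n <- max(length(lo), length(hi))
  if (length(lo) != n) lo <- rep_len(lo, n)
  if (length(hi) != n) hi <- rep_len(hi, n)
  lo <- as.double(lo); hi <- as.double(hi)
  if (anyNA(lo) || any(lo < 0 | lo > 1))
    stop("`lo` must lie in [0, 1]", call. = FALSE)
  if (anyNA(hi) || any(hi < 0 | hi > 1))
    stop("`hi` must lie in [0, 1]", call. = FALSE)
  if (any(hi < lo))
    stop("inverted endpoints: `hi` must be >= `lo`", call. = FALSE)
  new_iv(lo, hi)
}

# internal fast-path constructor: no validation
new_iv <- function(lo, hi) {
  structure(cbind(lo = lo, hi = hi), class = "iv")
}

#' @export
`[.iv` <- function(x, i, ...) {
  new_iv(unclass(x)[i, 1L], unclass(x)[i, 2L])
}

#' Endpoint and width accessors
#'
#' @param x an [iv] object.
#' @return Numeric vector: lower endpoints, upper endpoints, midpoints or
#'   widths `hi - lo`.
#' @export
iv_lo <- function(x) unname(unclass(x)[, 1L])

#' @rdname iv_lo
#' @export
iv_hi <- function(x) unname(unclass(x)[, 2L])

#' @rdname iv_lo
#' @export
iv_mid <- function(x) unname((unclass(x)[, 1L] + unclass(x)[, 2L]) / 2)

#' @rdname iv_lo
#' @export
iv_width <- function(x) unname(unclass(x)[, 2L] - unclass(x)[, 1L])

#' Number of intervals in an `iv` vector
#' @param x an [iv] object.
#' @return Integer count of intervals (matrix rows).
#' @export
iv_length <- function(x) nrow(unclass(x))

#' @export
format.iv <- function(x, digits = 17, ...) {
  paste0(formatC(iv_lo(x), digits = digits, format = "g"), ":",
         formatC(iv_hi(x), digits = digits, format = "g"))
}

#' @export
print.iv <- function(x, ...) {
  cat(sprintf("<iv[%d]>\n", iv_length(x)))
  cat(paste0("[", format(iv_lo(x), digits = 7), ", ",
             format(iv_hi(x), digits = 7), "]"), sep = "\n")
  invisible(x)
}

#' Parse intervals from their text serialization
#'
#' Inverse of `format()`: reads strings of the form `"lo:hi"` (decimal
#' endpoints) back into an [iv] vector.
#'
#' @param s character vector of `"lo:hi"` strings.
#' @return An [iv] object with one interval per input string.
#' @export
iv_parse <- function(s) {
  parts <- strsplit(as.character(s), ":", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad))
    stop("malformed interval string: ", s[bad][1L], call. = FALSE)
  m <- matrix(as.double(unlist(parts)), ncol = 2L, byrow = TRUE)
  iv(m[, 1L], m[, 2L])
}

#' Random intervals
#'
#' Samples intervals uniformly by drawing two independent `U(0,1)` endpoints
#' and sorting them. Used throughout the property-style checks.
#'
#' @param n number of intervals.
#' @return An [iv] vector of length `n`.
#' @export
riv <- function(n) {
  a <- stats::runif(n); b <- stats::runif(n)
  new_iv(pmin(a, b), pmax(a, b))
}

#' Interval comparison regimes
#'
#' Bundles one of the four comparison regimes on \eqn{L^I}:
#' \describe{
#'   \item{`partial2`}{the componentwise partial order
#'     \eqn{[a_-,a^+] \le_2 [b_-,b^+] \iff a_- \le b_- \wedge a^+ \le b^+};}
#'   \item{`admissible`}{a linear refinement of \eqn{\le_2} built
#'     lexicographically from two continuous aggregation functions
#'     \eqn{\Psi} (`psi`) and \eqn{\Upsilon} (`upsilon`) that jointly
#'     separate intervals; the default pair (midpoint, upper endpoint) is
#'     the conventional Xu–Yager-style instantiation;}
#'   \item{`possible`}{the epistemic relation
#'     \eqn{a \le_{pos} b \iff a_- \le b^+} ("the true value of `a` may be
#'     at most the true value of `b`"); strongly complete, not
#'     antisymmetric;}
#'   \item{`necessary`}{the ontic relation
#'     \eqn{a \le_{nec} b \iff a^+ \le b_-} (every value of `a` is at most
#'     every value of `b`); antisymmetric, transitive, Ferrers.}
#' }
#'
#' @param kind one of `"partial2"`, `"admissible"`, `"possible"`,
#'   `"necessary"`.
#' @param psi,upsilon vectorized functions of `(lo, hi)` returning a scalar
#'   key; only used by `kind = "admissible"`. They must jointly separate
#'   points: equal `psi` and equal `upsilon` imply an equal interval.
#' @param tol absolute tolerance used for floating-point equality of
#'   intervals and of `psi`/`upsilon` keys in [iv_compare()].
#' @return An object of class `order_spec`.
#' @examples
#' iv_leq(iv(0.2, 0.4), iv(0.3, 0.5), order_spec("partial2"))   # TRUE
#' iv_leq(iv(0.1, 0.2), iv(0.2, 0.5), order_spec("necessary"))  # TRUE
#' @export
order_spec <- function(kind = c("admissible", "partial2", "possible", "necessary"),
                       psi = function(lo, hi) (lo + hi) / 2,
                       upsilon = function(lo, hi) hi,
                       tol = 1e-12) {
  kind <- match.arg(kind)
  stopifnot(is.function(psi), is.function(upsilon), tol >= 0)
  structure(list(kind = kind, psi = psi, upsilon = upsilon, tol = tol),
            class = "order_spec")
}

#' Compare intervals under a comparison regime
#'
#' `iv_leq()` evaluates the regime's "less than or equal" relation
#' elementwise. `iv_compare()` derives a deterministic three/four-way
#' outcome from both directions: `"equal"` when the intervals coincide
#' within `order$tol` (or, under the possible relation, when both
#' directions hold, since \eqn{\le_{pos}} is not antisymmetric);
#' `"incomparable"` can only arise under `partial2` or `necessary`.
#'
#' @param a,b [iv] vectors (recycled to common length).
#' @param order an [order_spec].
#' @return `iv_leq()`: logical vector. `iv_compare()`: character vector with
#'   values in `c("less", "equal", "greater", "incomparable")`.
#' @export
iv_leq <- function(a, b, order = order_spec()) {
  n <- max(iv_length(a), iv_length(b))
  alo <- rep_len(iv_lo(a), n); ahi <- rep_len(iv_hi(a), n)
  blo <- rep_len(iv_lo(b), n); bhi <- rep_len(iv_hi(b), n)
  leq_lohi(alo, ahi, blo, bhi, order)
}

# vectorized kernel on raw endpoints; used by the classifier hot path
leq_lohi <- function(alo, ahi, blo, bhi, order) {
  switch(order$kind,
    partial2  = alo <= blo & ahi <= bhi,
    possible  = alo <= bhi,
    necessary = ahi <= blo,
    admissible = {
      pa <- order$psi(alo, ahi); pb <- order$psi(blo, bhi)
      tie <- abs(pa - pb) <= order$tol
      (pa < pb & !tie) | (tie & order$upsilon(alo, ahi) <= order$upsilon(blo, bhi) + order$tol)
    })
}

#' @rdname iv_leq
#' @export
iv_compare <- function(a, b, order = order_spec()) {
  n <- max(iv_length(a), iv_length(b))
  alo <- rep_len(iv_lo(a), n); ahi <- rep_len(iv_hi(a), n)
  blo <- rep_len(iv_lo(b), n); bhi <- rep_len(iv_hi(b), n)
  eq <- pmax(abs(alo - blo), abs(ahi - bhi)) <= order$tol
  ab <- leq_lohi(alo, ahi, blo, bhi, order)
  ba <- leq_lohi(blo, bhi, alo, ahi, order)
  out <- rep("incomparable", n)
  out[ab & !ba] <- "less"
  out[ba & !ab] <- "greater"
  out[eq | (ab & ba)] <- "equal"
  out
}

#' Interval negations
#'
#' A strong interval negation is an involutive, order-decreasing map
#' \eqn{N: L^I \to L^I} with \eqn{N([1,1]) = [0,0]} and
#' \eqn{N([0,0]) = [1,1]}. The standard negation
#' \eqn{N([x_-, x^+]) = [1 - x^+, 1 - x_-]} has equilibrium
#' \eqn{e = [0.5, 0.5]}; it is the default map for all three measure
#' families (`standard`, `possible`, `necessary`), each of which may be
#' re-pointed at a custom strong negation.
#'
#' @param family one of `"standard"`, `"possible"`, `"necessary"`; a label
#'   tying the negation to a measure family.
#' @param map function taking and returning an [iv] vector; must be a
#'   strong negation.
#' @param equilibrium the fixed point of `map` closest to `[0.5, 0.5]`.
#' @return An object of class `negation_spec`.
#' @examples
#' iv_negate(iv(0.2, 0.5))   # [0.5, 0.8]
#' @export
negation_spec <- function(family = c("standard", "possible", "necessary"),
                          map = NULL, equilibrium = NULL) {
  family <- match.arg(family)
  if (is.null(map)) map <- function(x) new_iv(1 - iv_hi(x), 1 - iv_lo(x))
  if (is.null(equilibrium)) equilibrium <- iv(0.5, 0.5)
  stopifnot(is.function(map), inherits(equilibrium, "iv"))
  structure(list(family = family, map = map, equilibrium = equilibrium),
            class = "negation_spec")
}

#' @param a an [iv] vector.
#' @param neg a [negation_spec].
#' @rdname negation_spec
#' @export
iv_negate <- function(a, neg = negation_spec()) neg$map(a)

#' Lattice join and meet
#'
#' The lattice operations of \eqn{(L^I, \vee, \wedge)}:
#' join \eqn{a \vee b = [\max(a_-, b_-), \max(a^+, b^+)]} and meet
#' \eqn{a \wedge b = [\min(a_-, b_-), \min(a^+, b^+)]}, with greatest
#' element `[1,1]` and least element `[0,0]`.
#'
#' @param a,b [iv] vectors (recycled).
#' @return An [iv] vector.
#' @export
iv_join <- function(a, b) {
  n <- max(iv_length(a), iv_length(b))
  new_iv(pmax(rep_len(iv_lo(a), n), rep_len(iv_lo(b), n)),
         pmax(rep_len(iv_hi(a), n), rep_len(iv_hi(b), n)))
}

#' @rdname iv_join
#' @export
iv_meet <- function(a, b) {
  n <- max(iv_length(a), iv_length(b))
  new_iv(pmin(rep_len(iv_lo(a), n), rep_len(iv_lo(b), n)),
         pmin(rep_len(iv_hi(a), n), rep_len(iv_hi(b), n)))
}
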