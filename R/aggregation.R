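#' Order-consistent interval aggregation
#'
#' An interval-valued aggregation function is increasing with respect to a
#' chosen comparison regime and maps all-`[0,0]` input to `[0,0]` and
#' all-`[1,1]` input to `[1,1]`. Four families are provided:
#' \describe{
#'   \item{`mean`}{componentwise arithmetic mean
#'     \eqn{[\mathrm{mean}(lo_i), \mathrm{mean}(hi_i)]}; increasing w.r.t.
#'     the componentwise partial order (and any admissible refinement);}
#'   \item{`pos`}{the possible-order-consistent aggregation: `[0,0]` when
#'     every argument is `[0,0]`, otherwise \eqn{[A(lo_1, lo_2), 1]} where
#'     `A` is a scalar `inner` aggregation (default arithmetic mean);}
#'   \item{`nec`}{the necessary-order-consistent aggregation
#'     \eqn{[(lo_1+lo_2)/2, \max((lo_1+hi_2)/2, (hi_1+lo_2)/2)]};}
#'   \item{`meet`}{the lattice meet \eqn{\wedge} (componentwise minimum),
#'     used as the default pairer inside similarity measures.}
#' }
#' The `pos` and `nec` families are defined pairwise; arities above 2 are
#' reduced by a left fold, which preserves the boundary conditions. The
#' `nec` fold is not associative, so the fold order (left-to-right) is part
#' of the contract.
#'
#' @param family one of `"mean"`, `"pos"`, `"nec"`, `"meet"`.
#' @param inner scalar aggregation on `[0,1]` used by the `pos` family:
#'   `"mean"`, `"min"`, `"max"` or `"product"`.
#' @return An object of class `aggregation_spec`.
#' @examples
#' iv_aggregate(iv(c(0.2, 0.6), c(0.4, 0.8)), aggregation_spec("mean")) # [0.4,0.6]
#' iv_aggregate(iv(c(0.2, 0.6), c(0.4, 0.8)), aggregation_spec("pos"))  # [0.4,1]
#' iv_aggregate(iv(c(0.2, 0.6), c(0.4, 0.8)), aggregation_spec("nec"))  # [0.4,0.5]
#' @export
aggregation_spec <- function(family = c("mean", "pos", "nec", "meet"),
                             inner = c("mean", "min", "max", "product")) {
  family <- match.arg(family)
  inner <- match.arg(inner)
  structure(list(family = family, inner = inner), class = "aggregation_spec")
}

# scalar inner aggregation, vectorized over paired arguments
inner_fun <- function(inner) {
  switch(inner,
    mean = function(x, y) (x + y) / 2,
    min = pmin,
    max = pmax,
    product = function(x, y) x * y)
}

# binary pos-aggregation on raw endpoints (vectorized)
agg_pos_lohi <- function(alo, ahi, blo, bhi, inner) {
  zero <- alo == 0 & ahi == 0 & blo == 0 & bhi == 0
  lo <- ifelse(zero, 0, inner_fun(inner)(alo, blo))
  hi <- ifelse(zero, 0, 1)
  list(lo = lo, hi = hi)
}

# binary nec-aggregation on raw endpoints (vectorized)
agg_nec_lohi <- function(alo, ahi, blo, bhi) {
  list(lo = (alo + blo) / 2, hi = pmax((alo + bhi) / 2, (ahi + blo) / 2))
}

#' Aggregate a vector of intervals
#'
#' @param values an [iv] vector (at least one interval).
#' @param spec an [aggregation_spec].
#' @return A single interval ([iv] of length 1).
#' @rdname aggregation_spec
#' @export
iv_aggregate <- function(values, spec = aggregation_spec()) {
  if (!inherits(values, "iv")) stop("`values` must be an iv vector", call. = FALSE)
  n <- iv_length(values)
  if (n == 0L) stop("cannot aggregate an empty interval vector", call. = FALSE)
  lo <- iv_lo(values); hi <- iv_hi(values)
  switch(spec$family,
    mean = new_iv(mean(lo), mean(hi)),
    meet = new_iv(min(lo), min(hi)),
    pos = {
      acc <- list(lo = lo[1L], hi = hi[1L])
      for (i in seq_len(n)[-1L])
        acc <- agg_pos_lohi(acc$lo, acc$hi, lo[i], hi[i], spec$inner)
      new_iv(acc$lo, acc$hi)
    },
    nec = {
      acc <- list(lo = lo[1L], hi = hi[1L])
      for (i in seq_len(n)[-1L])
        acc <- agg_nec_lohi(acc$lo, acc$hi, lo[i], hi[i])
      new_iv(acc$lo, acc$hi)
    })
}

#' Sampled monotonicity check for an aggregation family
#'
#' Draws random pairs of componentwise order-related interval tuples
#' \eqn{\zeta_i \le \eta_i} under `order` and counts violations of
#' \eqn{A(\zeta_1, ..., \zeta_m) \le A(\eta_1, ..., \eta_m)}. For the
#' matched pairs mean/partial2, pos/possible and nec/necessary the expected
#' violation count is 0.
#'
#' @param spec an [aggregation_spec].
#' @param order an [order_spec] under which both the premise and the
#'   conclusion are evaluated.
#' @param trials number of sampled tuple pairs.
#' @param arity tuple length.
#' @param seed integer seed for reproducibility.
#' @return A list with elements `trials`, `violations` and `arity`.
#' @export
check_monotonicity <- function(spec, order, trials = 1000, arity = 3, seed = 1) {
  stopifnot(trials >= 1, arity >= 2)
  with_seed(seed, {
    viol <- 0L
    for (t in seq_len(trials)) {
      zeta <- riv(arity)
      eta <- dominating_sample(zeta, order)
      az <- iv_aggregate(zeta, spec)
      ae <- iv_aggregate(eta, spec)
      if (!iv_leq(az, ae, order)) viol <- viol + 1L
    }
    list(trials = trials, violations = viol, arity = arity)
  })
}

# sample eta with zeta_i <= eta_i under the given regime
dominating_sample <- function(zeta, order) {
  n <- iv_length(zeta)
  lo <- iv_lo(zeta); hi <- iv_hi(zeta)
  switch(order$kind,
    possible = {
      # need eta_hi >= zeta_lo
      ehi <- lo + stats::runif(n) * (1 - lo)
      elo <- stats::runif(n) * ehi
      new_iv(elo, ehi)
    },
    necessary = {
      # need eta_lo >= zeta_hi
      elo <- hi + stats::runif(n) * (1 - hi)
      ehi <- elo + stats::runif(n) * (1 - elo)
      new_iv(elo, ehi)
    },
    {
      # componentwise domination serves partial2 and admissible
      elo <- lo + stats::runif(n) * (1 - lo)
      ehi <- pmax(elo, hi + stats::runif(n) * (1 - hi))
      new_iv(elo, ehi)
    })
}
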