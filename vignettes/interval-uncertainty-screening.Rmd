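---
title: "Interval uncertainty calculus and federated screening classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interval uncertainty calculus and federated screening classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivscreen)
```

## The model

`ivscreen` works on the lattice `L^I` of closed subintervals of `[0, 1]`.
An interval membership is read *epistemically*: it brackets one unknown
true value. A fuzzified questionnaire record is an interval-valued fuzzy
set (IVFS) over the attribute universe — a definite answer `a` on the
0–4 scale contributes the degenerate interval `[a/4, a/4]`, a missing
answer contributes `[0, 1]`. Nothing is imputed; the calculus propagates
the width of ignorance through every downstream comparison.

### Comparison regimes

Four regimes are available and deliberately kept distinct:

| kind | definition | character |
|---|---|---|
| `partial2` | `a⁻ ≤ b⁻` and `a⁺ ≤ b⁺` | partial order, lattice-native |
| `admissible` | lexicographic on `(Ψ, Υ)` | total, refines `partial2` |
| `possible` | `a⁻ ≤ b⁺` | strongly complete, not antisymmetric |
| `necessary` | `a⁺ ≤ b⁻` | antisymmetric, transitive, Ferrers |

The admissible order needs two continuous aggregation functions that
jointly separate intervals. The construction only prescribes the recipe,
not the pair; the package defaults to `Ψ = midpoint`, `Υ = upper
endpoint` — the conventional lexicographic instantiation — and keeps both
pluggable in `order_spec()`, since any experiment may reasonably choose
another admissible pair.

The possible relation is the *optimistic* reading (the true values might
be ordered this way), the necessary relation the *pessimistic* one
(every pair of true values is ordered this way). Because `≤pos` is not
antisymmetric, `iv_compare()` maps the mutual-`≤pos` case to `"equal"`:
ranking code needs a deterministic three-way outcome. Exact floating-
point ties are resolved within an absolute tolerance (default `1e-12`),
which matters because lexicographic orders are discontinuous at `Ψ`
ties.

### Aggregation, precedence, similarity

The classic interval mean, the pos-consistent and the nec-consistent
aggregations are implemented exactly as printed in their binary forms;
arities above two are reduced by a **left fold**. The fold order is part
of the contract: the nec form is not associative, so a different folding
would give different (still order-consistent) results.

Precedence indicators share one three-branch skeleton,

```
Prec(a, b) = [1 − w(a), 1]   if a = b
             [1, 1]          if a < b   (family's strict relation)
             Agg(N(a), b)    otherwise
```

with the family's negation `N` and aggregation `Agg` (`mean`, `pos`,
`nec`). Only the possible family's skeleton is fully printed in the
source material; the standard and necessary variants are constructed
here by substituting the family's order, negation and aggregation into
the same skeleton. This choice is flagged as a reconstruction: it
satisfies the symmetry, idempotency and monotonicity properties the
entropy propositions rely on, and each branch stays pluggable through
`precedence_spec()`.

Strictness in the second branch means "related and not equal". Under the
possible relation this makes two distinct overlapping intervals saturate
at `[1, 1]` in *both* directions — intended optimistic semantics, with a
visible consequence: a missing answer that overlaps the query value does
not reduce the possible-family similarity at all, while the standard
family registers the epistemic loss. Both behaviours are tested.

Similarity pairs the two precedence directions with a commutative pairer
(default: the lattice meet, as printed) and aggregates across universe
elements (default: componentwise mean). Symmetry is then structural.

### Interval entropy

All three entropy families are realized by one construction: the
similarity between a set and its pointwise negation,
`E(A) = S(A, A^N)`. The axioms are:

* `E(A) = [0, 0]` exactly when `A` is **classical** (memberships in
  `{[0,0], [1,1]}`);
* `E(E) = [1 − w(e), 1]` for the constant map at the negation's
  equilibrium `e` (with the standard negation `e = [0.5, 0.5]`, so
  `[1, 1]`);
* monotonicity toward `e` under the family's order;
* for the standard family, stability under negation `E(A) = E(A^N)`.

Two modelling decisions deserve emphasis. First, "crisp" in the zero-
entropy axiom is implemented as *classical*, not merely degenerate: a
degenerate `[0.5, 0.5]` membership is maximally fuzzy, and treating all
degenerate intervals as crisp would contradict the equilibrium axiom.
Degeneracy in the narrow width sense remains available as
`iv_width(x) == 0`. Second, all three families default to the standard
negation `N([x⁻, x⁺]) = [1 − x⁺, 1 − x⁻]`; dedicated possible/necessary
negations are not printed in the source material, and the entropy
examples there are exercised against the standard negation. A custom
strong negation (with its equilibrium) can be supplied via
`negation_spec()`; when a supplied negation has several fixed points the
intended equilibrium is the one closest to `[0.5, 0.5]` in Moore
distance, and it is the caller's declaration.

The axiom suite (`entropy_axiom_suite()`) replays the axioms as sampled
property checks. Monotonicity pairs are drawn from the *interior* of
`L^I`: at boundary configurations containing exactly crisp memberships
the possible-family similarity construction can violate the letter of
the monotonicity axiom (e.g. `A = {[0, 0.6]}`, `B = {[0, 0]}` gives
`E(A) = [1,1]`, `E(B) = [0,0]`), a measure-zero set under continuous
sampling. The suite therefore verifies generic behaviour, which is what
the classifier relies on; the boundary caveat is a known limitation of
the similarity-based construction, not of the sampling.

## The classifier

`iv_knn()` is a kNN scheme in interval space:

1. **Similarity ranking.** The query is compared with every training
   record on the condition attributes (default 1–20; the verification
   items 21–22 are excluded). Ranking under a partial regime proceeds by
   iterative extraction of maximal elements; ties are broken by smaller
   similarity width, then smaller record id. Both the per-class reading
   (top `k` within each decision class, the default) and the global
   reading (top `k` overall, then per class) of the neighbour-selection
   step are implemented, since the narrative supports either.
2. **Entropy selection.** Among a class's top `k`, the representative is
   the record with minimal object entropy — the least uncertain
   neighbour — under the configured order.
3. **Decision cascade.** With evidence intervals `d0` and `d1` (the
   representatives' similarities): a single present class wins; a strict
   order relation decides; otherwise the unique class at-or-above the
   neutral `[0.5, 0.5]` while the other is below wins; otherwise the
   narrower interval wins; otherwise the classifier abstains (`"ND"`).
   The cascade is a reconstruction from prose, so every rule is
   inspectable (`rule` column of `predict()`).
4. **Verification override.** A definite answer below 2 on either
   reverse-scored verification item overrides a non-risk or abstained
   outcome to the risk class. Missing verification answers never
   trigger; a risk label is never changed.

An abstention that survives verification stays an abstention; it is
penalized in the metrics (below), never silently dropped.

## Federation

Clients train locally and are all evaluated on one shared balanced test
pool. The federated decision is the plurality of local labels
(abstentions do not vote); a tied vote goes to the label whose
supporting clients contain the minimal representative entropy under the
configured order, with residual ties resolved by entropy midpoint and
then client index. The decision rule gates adoption: only clients whose
local gating metric (default accuracy) is *strictly below* the
federation's adopt the federated decisions. Consequently each client's
post-rule gating metric equals `max(local, federated)` on the shared
pool — an exact, by-construction property the tests re-verify by
recomputation. The gate is computed on the shared pool because it is the
only evaluation set common to all parties.

Metrics are the standard screening quartet (ACC, SENS, SPEC, PREC);
zero-denominator cases are reported as `NA` and flagged, not coerced to
zero. An abstention counts as a false negative when the truth is
positive and as a false positive otherwise.

## The synthetic generator

`generate_synthetic()` emulates the profile of the screening survey the
method targets: 750 records, exactly 249 positive decisions, and about
5% missing cells, uniformly across items (the source profile does not
say whether missingness concentrates; uniform is the neutral choice).
Class counts are pinned exactly rather than drawn, so fixture targets
are deterministic.

A latent severity `s ~ N(0, 1)` (class 0) or `N(effect_size, 1)`
(class 1) drives all answers: risk items discretize `1 + s + ε` onto
`{0..4}` and verification items discretize `3 − s + ε` (reverse scored),
with item noise `ε ~ N(0, 0.75)`. The default `effect_size = 2` — a
two-latent-SD class separation — is what we consider a realistic
signal for a screening instrument designed to discriminate; it makes a
trivial sum-score threshold reach roughly 83% accuracy, leaving
meaningful headroom for the interval method while keeping the federated
comparisons informative.

What the generator does *not* emulate: item-level factor structure
(one common severity factor only), response styles, informative
missingness, and label noise from an imperfect reference test. Passing
tests on synthetic data therefore demonstrate algorithmic correctness
and the qualitative federation effect, not clinical performance on real
questionnaires.

### NON-IID splitting

The three-client design removes a class-balanced 15% test pool first,
then forms clients with class-1 shares 50%, 20% and 80%. With a 501/249
class imbalance it is arithmetically impossible to keep the clients
equal-sized, hit those mixes exactly, *and* use every record: equal
thirds of the remaining 638 records would require 318 positives when
only 193 remain. The package keeps the stated mixes and equal client
sizes — these are the experimental conditions being emulated — at the
largest feasible common size (128 per client on the defaults) and
returns the leftover records as `unused`. Disjointness of all parts is
preserved and tested.

## Problem sizes and numerical choices

The shipped tests exercise the structural laws on 10^4 random
pairs/triples/quadruples, the entropy axioms on 10^3 sampled IVFSs per
family, classifier-vs-reference equivalence on 200 toy datasets (3–8
training records, 4 condition attributes, all four order kinds, both
neighbour strategies, all three measure families), and the federation
properties on the full 750-record profile over 10 repeated NON-IID
splits. Equality of intervals is asserted exactly where the algebra is
exact (crisp entropy, boundary conditions) and at `1e-9`–`1e-12`
absolute tolerance where floating-point accumulation is involved. All
randomness is seeded; scenario repetitions derive per-repetition seeds
from one master seed.

## Known limitations

* The standard/necessary precedence and similarity forms are principled
  reconstructions (shared skeleton), not transcriptions of unpublished
  formulas; they are clearly separated behind `precedence_spec()` and
  `similarity_spec()`.
* The possible-family entropy monotonicity axiom can fail on crisp
  boundary configurations (see above).
* The decision cascade's neutral-value rule is unreachable under the
  componentwise and admissible regimes (a strict relation always fires
  first there); it is live under the possible regime.
* Verification-question semantics assume the 0–4 scale; other scales
  require re-deriving the 0.5 threshold.
* The federated layer exchanges labels and representative entropies
  only. It is a decision-level federation; no parameter averaging or
  formal privacy accounting (e.g. differential privacy) is provided.
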