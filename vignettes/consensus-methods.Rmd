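---
title: "Consensus combination of rank classifiers: models, solvers, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus combination of rank classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rankfuse)
```

## The model

An ensemble of `M` rank classifiers assigns each of `K` classes a rank in
`1..K`, smaller rank meaning more likely; every classifier's output is a
total order, i.e. a permutation. The package's central object is the
`rank_matrix`, the `K x M` table of these ranks, validated so that every
column is a permutation (ties and partial rankings are rejected — the exact
solvers below rely on total orders, and silently accepting ties would change
the combinatorial structure of both problems).

The consensus ranking is the total order `r*` minimising
`sum_k f(r, r^(k))` over all `K!` orders. Two counting metrics are
supported, and each reduces the minimisation to a binary linear program over
a tally matrix computed once from the ensemble:

* **Disagreement** (`f_d`, Hamming on positions): with the *position tally*
  `pi[i, j]` = number of classifiers placing class `i` at position `j`, the
  objective is `sum_ij (M - pi[i, j]) x[i, j]` over permutation matrices.
  The constraint set is the assignment polytope, whose vertices are exactly
  the permutation matrices, so the relaxation is tight and the problem is
  solvable in polynomial time — the "binary programming" form is not
  actually hard in this case.
* **Condorcet** (`f_C`, Kendall tau): with the *pair tally*
  `delta[i, j]` = number of classifiers preferring class `i` to class `j`,
  minimising `phi_C` is equivalent to maximising `sum_ij delta[i, j]
  y[i, j]` over the pairwise codes of total orders (antisymmetry
  `y_ij + y_ji = 1` plus transitivity). This is the linear ordering
  problem, NP-hard in general.

`phi_C` relates to the vote score through the constant
`theta = M K (K - 1) / 2`: `phi_C(r) = theta - sum delta[i,j] y[i,j]`. All
objectives, distances and tallies are integers and are kept in integer
arithmetic throughout; the conjunction coefficients perform a single
floating-point division at the end. This removes any possibility of
floating-point drift deciding between two candidate optima.

### A note on the metric inequality

For any two total orders, `f_d(r, s) <= sum_i |r_i - s_i| <= 2 f_C(r, s)`.
The stronger one-line claim `f_d <= f_C` sometimes attached to this chain is
false: an adjacent transposition has `f_d = 2` but `f_C = 1`. The test suite
asserts the derivable two-sided chain (exhaustively for `K <= 4`, on 10^4
random pairs up to `K = 8`) and includes the adjacent-swap counterexample.

## Solvers

**Disagreement.** A Jonker–Volgenant shortest-augmenting-path assignment
solver (`lap_solve()`, written in R; `O(K^3)`). Because several assignments
can be optimal, the returned ranking is made deterministic by a
lexicographic refinement: positions are fixed class by class to the smallest
position that still admits an optimal completion (verified by re-solving the
reduced assignment). This costs at most `K^2` extra `O(K^3)` solves —
negligible at the intended scale.

**Condorcet.** Three regimes:

* `K <= 8`: exhaustive, vectorised evaluation of all `K!` orders. This also
  powers `enumerate_optima()`, which lists *all* optimal orders and makes
  tie-breaking auditable.
* `8 < K <= 15`: branch-and-bound over prefix orders (choosing the class for
  the next-best position), pruned with the admissible bound that every pair
  not yet ordered contributes `max(delta_ij, delta_ji)`. All optima are
  collected (up to a cap of 4096) so the same tie-break applies.
* `K > 15`: a capability error. No heuristic fallback is offered — an
  approximate "consensus" silently replacing the exact one would defeat the
  purpose of an exact method. An integer-programming backend would be the
  natural extension here.

**Tie-breaking.** Among Condorcet-optimal orders the solver prefers the
order maximising the disagreement-metric vote score `sum_i pi[i, r_i]` (how
many classifiers voted each class into exactly its consensus position),
breaking remaining ties by the lexicographically smallest rank vector. The
secondary vote score is this package's reconstruction of the selection
implicit in the classical worked example: on the shipped 10-digit instance
the pair {digit 1, digit 2} is majority-tied 2–2, both swaps are optimal,
and plain lexicographic order would pick the *other* one; the vote score
(digit 2 has two first-place votes, digit 1 one) selects the reference
column. The disagreement solver breaks ties lexicographically. Both solvers
are fully deterministic; `optimum_count_hint` and `tiebreak_applied` in the
result report whether a tie existed.

## Conjunction coefficients

`I_C` is computed from the pair tally exactly as defined:
`4 sum delta(delta-1) / (M(M-1)K(K-1)) - 1`. It is the probability that two
distinct classifiers drawn at random agree on the orientation of a random
class pair, rescaled from `[1/2, 1]` to end at 1 for a unanimous ensemble.

`I_d` is defined here as `sum pi(pi-1) / (K M(M-1))` — the *positional*
analogue of the same pair-counting construction: the probability that two
distinct classifiers agree on the exact position of a random class. **This
formula is this package's own construction**: only the interval `[0, 1]` of
the disagreement-metric coefficient is classically stated, without an
explicit formula. The reconstruction satisfies every stated property — it is 1 iff
all rankings are identical, 0 iff no (class, position) cell receives two
votes (e.g. cyclic-shift ensembles), and exhaustive enumeration over all
profiles for `(M, K)` in `{2,3} x {3,4}` confirms it never leaves `[0, 1]`.

**Attainable interval of `I_C`.** The most balanced pair tally a profile of
total orders can produce has every `delta[i, j]` as close to `M/2` as
possible (e.g. half the classifiers ranking in one order and half in its
reverse), giving a minimum of `-1/(M-1)` for even `M` and `-1/M` for odd
`M`. The interval is classically printed with the opposite parity
assignment; since exhaustive enumeration of all `(K!)^M` profiles (for `M`
in `{2,3}`, `K` in `{3,4}`) contradicts it and supports the
balanced-profile computation, `ic_bounds()` returns the enumeration-backed
interval, exposes the classical one as `printed_lower`, and flags the
discrepancy.

## The simulator

`simulate_ensemble()` generates the statistical situation the pipeline is
meant for: per sample a true class is drawn from `class_priors`, and each
classifier produces a noisy ranking centred on an order that puts the true
class first (remaining classes in canonical index order, so center-recovery
experiments are well defined).

* **Noise models.** `"mallows"` draws from a Mallows distribution
  `P(r) ∝ exp(-dispersion * f_C(r, center))` via the repeated-insertion
  construction — an exact sampler, no MCMC burn-in to tune; `dispersion = 0`
  is uniform, large values collapse onto the center. `"score"` draws
  Gaussian class scores with the true class shifted by `accuracy` and
  converts them with `scores_to_ranks()`, mimicking margin-based
  classifiers.
* **Dependence.** Real ensembles err together on hard samples. With
  `dependence > 0` a per-sample shared noise component is mixed in: under
  the Mallows model each classifier adopts a shared noisy ranking with
  probability `dependence`; under the score model the score noise has
  correlation `dependence` across classifiers. `dependence = 0` gives
  conditionally independent classifiers.
* **Defaults.** `K = 3` classes with priors `(0.81, 0.02, 0.17)` — a
  normal / atypical / debris mix with a rare positive class, matching the
  class shares reported for the cervical-smear screening setting this
  package's pipeline is modelled on; `positive_class = 2` (the rare class), because
  false negatives and false positives carry asymmetric clinical risk and the
  designation must be explicit, never implicit.
* **Determinism.** Every sampling function takes an explicit seed and
  restores the caller's RNG state; the same configuration reproduces the
  same batch bit-for-bit.

What the simulator does *not* emulate: feature extraction and real
classifier training (its "classifiers" are exchangeable noise processes with
a known center), heterogeneous per-classifier accuracy, and structured
confusions between specific classes. Passing simulation tests therefore
demonstrates the correctness and statistical behaviour of the combination
machinery, not the performance of any real classifier stack.

## Evaluation conventions

`evaluate_predictions()` reports `error_rate = misclassified / n`,
`FPR = FP / N` and `FNR = FN / P` relative to the named positive class.
When a batch contains no negatives (or no positives) the corresponding rate
is `NA`, never silently 0. Confusion-matrix rank likelihoods
(`rank_likelihoods()`) are exposed as diagnostics only: using them as a
fusion rule would require knowing the true class at prediction time.
`pairwise_independence_gap()` and `marginal_decision_probability()` exist to
make a classical point testable: under equal priors a symmetric binary
classifier's marginal decision probability is 1/2 regardless of its
accuracy, so unconditionally independent classifiers are necessarily random
ones, and useful ensembles are dependent by construction — conditional
independence given the class is the meaningful notion.

## Problem sizes used by the test suite

Exhaustive checks run at the scale where exhaustion is honest: all `K!`
orders for `K <= 7` against 500 random instances (solver-vs-oracle
equivalence), all `(K!)^M` profiles for `(M, K)` in `{2,3} x {3,4}`
(coefficient intervals), all permutation pairs for `K <= 4` plus 10^4
random pairs (metric inequality). Stochastic properties use fixed seed
blocks: center recovery at `K = 5`, dispersion 0.5, 200 replicates of
`M = 101` (expected recovery ≥ 95%), and the ensemble-size effect with 20
replicates each at `M = 3` and `M = 25`. These sizes were chosen as the
smallest at which each property is sharply testable.

## Known limitations

* No weighted classifiers: all ensemble members count equally in both
  tallies. Weighting would be a natural extension of both tally
  constructions.
* No partial orders, tied ranks, or top-t lists — by design, not oversight.
* The Condorcet solver's exact ceiling is `K = 15` without an integer
  programming backend.
* `I_d` is this package's own construction (documented above), not an
  inherited formula.
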