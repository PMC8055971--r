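---
title: "Methods: epsilon-PAL active learning for polymer design spaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: epsilon-PAL active learning for polymer design spaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epal)
```

## Problem setting

Designing a polymeric dispersant means trading off at least three
properties at once — how strongly it adsorbs to the particle surface
(adsorption free energy), how strongly coated particles repel each other
(dimer repulsion barrier), and how much it thickens the formulation
(radius of gyration as a viscosity proxy). No single ranking of candidates
is unbiased in such a multiobjective setting; the only rigorous target is
the Pareto front. When each property measurement is an expensive
simulation or experiment, the practical question becomes: classify every
member of a finite candidate library as Pareto-optimal-within-tolerance or
confidently discardable, using as few measurements as possible.

`epal` implements the ε-PAL answer: Gaussian-process confidence
hyperrectangles plus ε-tolerant dominance rules, with a
coefficient-of-variation acquisition rule deciding what to measure next.

## The design space and its featurization

The candidate library is produced by a full-factorial design of
experiments over the four coarse-grained bead types `W` (good solvent),
`R` (bad solvent) and `Ta`/`Tr` (theta solvent, differing in surface
affinity). Factors are the bead types, levels the allowed per-type counts
(default 4, 6, 8, 10, 12), and each composition is expanded into 5
distinct random monomer arrangements: `5^4 × 5 = 3125` polymers.
Uniqueness of arrangements is enforced by redrawing (up to 1000 times —
the generator errors if a composition, e.g. a homopolymer, cannot support
the requested number of distinct arrangements).

Each sequence is featurized into a fixed-order vector: degree of
polymerization `N`; relative sequence entropy (Shannon entropy of the
type frequencies in natural log, always normalized by `log 4` over the
fixed alphabet so values are comparable across polymers regardless of how
many types a sequence actually uses); one-hot head **and** tail end groups
(8 binary columns — "end groups" is read as both termini); per-type
counts; the summed interaction parameter `Σ_i a(bead_i)` over a
user-supplied 4-entry table (the shipped table holds documented
placeholder values, since force-field-calibrated ones are not available to
the package; every code path takes the table as input); and run-length
"cluster" statistics (total number of maximal runs, mean and maximum run
length, and per-type run counts). Features are z-scored with
training-set-only statistics — population standard deviation, matching the
common machine-learning convention — and zero-variance columns map to 0
rather than NaN so constant features cannot poison the kernel. Inside a
campaign the standardization statistics come from the initial design
sample and are then frozen: refreshing them at every refit would silently
change the metric under the kernel mid-campaign and preclude cheap
conditioning updates; the learned lengthscale absorbs residual scale
drift.

## The coregionalized surrogate

A single intrinsic-coregionalization-model (ICM) Gaussian process covers
all objectives. Observations are stacked `(feature vector, objective
index)` rows with kernel

```
k((x, o), (x', o')) = B[o, o'] · k_Matérn-5/2(‖x − x'‖ / ℓ),   B = w wᵀ + diag(κ),
```

rank 1 by default (rank 2 selectable; more latent functions mean more
hyperparameters and harder optimization). A candidate with missing
objectives simply contributes fewer rows, and the missing objective is
predicted through the cross-objective covariance in `B` — this is what
lets campaigns continue when a third of one objective's labels are
unmeasurable. Labels are z-scored per objective internally (objectives
live on very different scales) and predictions are de-standardized.
Per-label known noise enters as fixed heteroscedastic variance; labels
without a stated noise share a learned per-objective term. A `1e-6`
diagonal jitter stabilizes the Cholesky factorization.

Hyperparameters maximize the marginal likelihood by L-BFGS-B with seeded
random restarts (default 5). Because a full re-optimization is the
expensive step, it fires on a schedule — after every 10 added labels by
default ("regular intervals") — while other updates re-condition the
posterior at fixed hyperparameters, which is cheap and can only shrink
predictive variance. Latent hyperparameters are re-initialized at every
refit (the restart base point is data-driven); whether they should instead
be warm-started is genuinely open, and the seeded-restart scheme makes
either choice reproducible. No GP library ships with the intended
environment, so the model is implemented directly with dense Cholesky
algebra; for the stacked sizes this package targets (≤ ~1500 rows) that is
faster than any approximation would be worth.

## The classification loop

All objectives are oriented internally as maximization (minimized
objectives are negated at ingestion and re-negated on output — a single
orientation keeps every dominance rule one-sided). Each iteration `t`:

1. predict `μ, σ` for all candidates; build per-candidate hyperrectangles
   `μ ± √β_t σ`, where sampled (candidate, objective) pairs use the
   measured value and its measurement noise instead. `β_t = β_scale · 2
   log(m n π² t² / (6δ))` is the union-bound schedule of the original
   ε-PAL analysis; `β_scale` defaults to the common practical deflation
   1/9, with 1 recovering the theoretical scaling. Rectangles are
   intersected with their predecessors so uncertainty never grows; an
   empty intersection (a model refit moved its mean outside the old box)
   falls back to the fresh interval with a warning — the property tests
   treat exactly those flagged repairs as the only admissible width
   increases.
2. discard any unclassified `x` for which some alive `x'` satisfies
   `pess_i(x') + ε_i |μ_i(x')| ≥ opt_i(x)` in every objective, strictly in
   at least one. The strict part is deliberate: with weak inequalities
   only, two candidates with *identical* objective vectors would discard
   one another arbitrarily at ε = 0, contradicting the exact-Pareto
   convention that ties are all kept. Whenever `ε_i |μ_i| > 0` or values
   are generic the strict and weak forms coincide.
3. promote any unclassified `x` no alive candidate could still beat:
   there is no `x'` with `opt_i(x') ≥ pess_i(x) + ε_i |μ_i(x)|` in every
   objective (strictly in one). Discarded points never return; promoted
   points never return to unclassified.
4. sample the unsampled candidate in `P ∪ U` with the largest
   dimensionless rectangle `w(x) = max_i (upper_i − lower_i) / |μ_i|`
   (ties to the lowest index, batch sampling supported, default batch 1).
   Discarded candidates are never sampled, however uncertain. Denominators
   `|μ_i| < 1e-8` are clamped to that tolerance: the mean-scaled scheme
   presupposes sign-stable objectives, and objectives crossing zero would
   otherwise yield infinite weights (a documented caveat, not a silent
   fix). An `exclude_high_variance` option can additionally keep
   extreme-`w` candidates out of the classification stage for one
   iteration.

The campaign stops when every candidate is classified **and** every
Pareto-classified candidate has been sampled, at `max_iterations`, or —
for benchmark runs with known ground truth — when the hypervolume error of
the classified front reaches a stated target (`hv_stop`), which is how the
scaled-down efficiency comparisons keep within desk-scale budgets. After
the loop the surrogate is retrained once on all sampled points, including
discarded ones. The mean-scaled tolerance interacts with measurement
noise: a sampled point whose `2√β_t · noise_sd` exceeds `ε_i |μ_i|` can
become permanently unclassifiable once nothing is left to sample, so
tolerances should exceed the oracle's error — the benchmark noise defaults
are set accordingly (~1% of typical magnitudes against the default
ε = 0.05).

## Hypervolume accounting

Fronts are scored by the hypervolume indicator — the Lebesgue measure of
the union of boxes between a reference point and each front member —
computed exactly for up to three objectives (2-D sweep; 3-D by slicing
along the third objective), with a seeded Monte-Carlo estimator as an
independent cross-check and as the d > 3 fallback. The reference point is
the nadir of the true front (per-objective worst over the Pareto subset —
dominated points deliberately do not influence it). The hypervolume error
of a campaign is `(HV_max − HV_current)/HV_max`, where only candidates
*classified* as ε-accurate Pareto-optimal count toward `HV_current` (so
early iterations of a tight-ε campaign can sit at error 1), while the
random-search baseline is scored on the true-Pareto subset of whatever it
has sampled — the only sensible reading for a method that never
classifies anything.

## What the synthetic world does and does not establish

The pseudo-simulator replaces the molecular-dynamics oracle with analytic
trends: `Rg = a N^ν_eff` with `ν_eff` a composition-weighted blend of
textbook Flory exponents (0.588 good / 0.5 theta / 1/3 collapsed);
adsorption strength as summed per-bead surface affinities (lowest for `W`)
plus an end-anchoring bonus; repulsion increasing in the good-solvent bead
count, the relative sequence entropy, and weakly the number of runs; plus
additive Gaussian noise that is a deterministic function of (seed,
sequence). The coefficients are invented emulations of the reported
qualitative structure–property trends, not calibrated to any force field —
a green test therefore establishes that the *algorithm* behaves correctly
(classification, efficiency vs random search, missing-data handling),
never that these polymers are good dispersants.

Two stochastic-guarantee subtleties are worth stating plainly. First, the
`(1 − δ)` ε-accuracy guarantee is proved for a *correct* model with the
undeflated β schedule; the acceptance test of that guarantee therefore
draws objectives from the surrogate's own prior, hands the campaign the
true kernel hyperparameters (`fit_surrogate(theta = ...)`) and sets
`β_scale = 1`. With hyperparameters instead learned from a handful of
points and the practical 1/9 deflation, measured coverage drops a few
points below `1 − δ` (tiny margins, 1–25% of the tolerance) — a real and
documented property of the practical regime, not a code defect. Second,
the GA-inversion finding that proposals cannot dominate the discovered
front only transfers to worlds whose optimum the design of experiments
actually covers; with sequence-level terms active, five random
arrangements per composition do not cover the sequence optimum, so the
corresponding test uses a composition-determined variant of the simulator
on a consecutive-level design whose composition hull the GA cannot leave.

## Inverting the model

`distill_surrogate()` fits a gradient-boosted regression-tree model
(hand-written: greedy variance-reduction splits, depth 3, shrinkage 0.1 —
no boosting library exists in the intended environment) to the GP means
over the design space, on a *reduced, invertible* feature schema: counts,
end groups, degree of polymerization, summed interaction, total run count
— dropping the relative entropy and the non-invertible run statistics. The
elitist GA (tournament selection, uniform crossover, bounded ±2 integer
mutation, top fraction copied unchanged so best fitness is monotone)
maximizes `prediction − novelty_weight · exp(−d²/ℓ²) − invalid_penalty ·
[undecodable]`, where `d` is the minimum standardized distance to the
design set. One GA run targets one objective (or an explicit weight
vector): the package does not guess how three objectives were scalarized,
and the choice is surfaced in the API. Count genes are bounded by the
per-type ranges observed in the design. Each elite vector is decoded into
up to 3 sequences by `backtrace_sequence()` — a randomized constructor
that allocates run counts per type, arranges run labels with pinned ends
and no equal neighbours, splits counts across runs, and verifies the
invertible features match exactly; inconsistent vectors (non-integer or
negative counts, end groups absent from the counts, infeasible run
totals) return INVALID as a value for the GA to penalize.
`evaluate_discoveries()` then scores decoded proposals with the oracle and
flags any that Pareto-dominate the campaign front.

## Numerical and reproducibility choices

One master seed drives everything through a Lehmer-style splitting scheme
(`derive_seed()`); campaigns, benchmarks, the GA and the Monte-Carlo
estimator are bit-reproducible given (config, seed), which is also how
`cmd_run(resume = TRUE)` re-derives an interrupted run exactly. Package
randomness runs on isolated RNG streams that never touch the caller's
`.Random.seed`. CSV output is pinned to comma/UTF-8/LF so identical runs
are byte-identical. Known limitations: exact hypervolume is d ≤ 3
(Monte-Carlo beyond); the candidate library must be finite; mean-scaled
tolerances assume sign-stable objectives; and campaign resumability
re-derives rather than deserializes the surrogate state.
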