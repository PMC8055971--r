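# epal — confident Pareto-front discovery for discrete materials libraries

`epal` implements the ε-PAL (Pareto Active Learning) workflow for
multiobjective design over a *finite* candidate library, in the setting of
coarse-grained polymer dispersant design: when each property evaluation is
an expensive simulation or experiment, the goal is not to rank materials
(which injects bias) but to classify, with confidence, **every** candidate
as ε-accurate Pareto-optimal or confidently discarded, using as few oracle
evaluations as possible.

## The algorithm

For each candidate `x` and objective `i` (all oriented as maximization) the
surrogate supplies a posterior mean `μ_i(x)` and standard deviation
`σ_i(x)`, giving a confidence hyperrectangle

```
Q_t(x) = ∏_i [ μ_i(x) − √β_t σ_i(x),  μ_i(x) + √β_t σ_i(x) ],
β_t = β_scale · 2 log( m n π² t² / (6δ) ),
```

intersected across iterations so it can only shrink; measured points use
their measurement noise instead of the model σ. With per-objective
tolerances ε_i, mean-scaled as ε_i·|μ_i|:

* **discard** `x` when another alive candidate's pessimistic corner,
  inflated by its tolerance, dominates `x`'s optimistic corner;
* **promote** `x` to the ε-accurate Pareto set when no alive candidate
  could dominate it even optimistically;
* **sample** next the unsampled candidate near the front with the largest
  dimensionless rectangle `w(x) = max_i (upper_i − lower_i)/|μ_i|`
  (a coefficient-of-variation acquisition rule).

The loop ends when everything is classified (with probability ≥ 1 − δ the
result is ε-accurate when β is scaled properly). The surrogate is an
intrinsic-coregionalization (ICM) multi-output Gaussian process on a
Matérn-5/2 kernel — objectives share one latent function through
`B = w wᵀ + diag(κ)` — so candidates with *missing* objective labels still
borrow strength from the measured ones.

Around the loop the package provides: full-factorial generation and
featurization of polymer sequence design spaces, exact (d ≤ 3) and
Monte-Carlo hypervolume indicators with nadir-referenced hypervolume error,
a bootstrapped random-search baseline, a noisy three-objective
pseudo-simulator (Flory-scaling radius of gyration, surface-affinity
adsorption strength, entropy-driven dimer repulsion), and an elitist
genetic algorithm that inverts the trained surrogate through a
boosted-tree distillation and a feature→sequence back-tracing decoder.

## Worked example

```r
library(epal)

prob <- make_benchmark("three_obj_polymer", size = 324, seed = 1)
cfg <- epal_config(epsilon = rep(0.05, 3),
                   objective_directions = prob$directions,
                   init_size = 20, max_iterations = 120, hv_stop = 0.05)
camp <- run_campaign(prob$design, prob$oracle, cfg, seed = 101,
                     truth = prob$truth)
glance(camp)
#> # A tibble: 1 × 7
#>   iterations n_pareto n_discarded n_unclassified n_evaluations hypervolume_error natural_stop
#>        <int>    <int>       <int>          <int>         <int>             <dbl> <lgl>
#> 1          8       42         239             43            27            0.0443 FALSE
```

After 8 learning iterations (27 oracle evaluations including the
20-sample farthest-point initialization) the classified front already
covers 96% of the attainable hypervolume (error 0.044 ≤ the 0.05 stop
target); 239 of 324 polymers are confidently discarded without ever being
simulated. A matched random-search baseline
(`random_search_baseline(prob, 324, 100, seed = 101, init = ...)`)
needs 196 evaluations (bootstrap mean) to reach the same error. `tidy(camp)`
returns the per-candidate classification, `autoplot(camp)` the progress
curves, and `invert_surrogate(camp$model, prob$design)` proposes new
sequences from the trained model.

A command-line interface over the same functions is installed at
`inst/cli/epal-cli.R` (`generate-design`, `run`, `baseline`, `invert`).

## Acceptance script

`scripts/acceptance.R` re-runs the main pipeline from scratch against the
installed package — the 3125-polymer full-factorial design space, a
desk-scale three-objective ε-PAL campaign with its matched random-search
baseline, and a GA inversion of the trained surrogate — and writes the
machine-readable report to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
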