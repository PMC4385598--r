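---
title: "Methods: GA-initialized backpropagation for porcelain recipe prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GA-initialized backpropagation for porcelain recipe prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shadematch)
```

## The problem and the model

A fired dental ceramic specimen's color, measured as a CIELAB triple, is a
smooth but nonlinear function of the mixing proportions of the dentin
powders it was made from. Recipe prediction inverts that map: given a
target `(L*, a*, b*)`, produce the five mass fractions (A1, A4, B4, C4,
D4). The package models the inverse directly with a three-layer
feed-forward network — 3 inputs, `h` hidden neurons, 5 outputs — because a
single nonlinear hidden layer is sufficient for function approximation of
this kind and keeps the parameter count (113 at `h = 12`) small enough to
train on a hundred specimens.

Every neuron computes `o = f(net / λ)` with `net = Σ w·x − θ` (the
threshold is *subtracted*; only consistency matters for learning, and the
convention is fixed throughout the package, including the chromosome
encoding). `f` is either the logistic sigmoid (outputs in (0, 1)) or the
tangent sigmoid (outputs in (−1, 1)); a linear activation exists purely
as a testing hook for closed-form checks. The gradient factor `λ ≥ 1`
divides the net input, and its `1/λ` carries through the chain rule
(`f' = o(1−o)/λ` for the logistic case) — the finite-difference oracle in
the test suite checks exactly this.

## Training loop decisions

Training is **full batch**. The adaptive learning-efficiency rule judges
each adjustment by the *total error* of a complete pass, which is only
well defined per epoch; full-batch updates make its rollback semantics
coherent.

The loop per epoch: compute the gradient, form the momentum step
`ΔW_t = η·(−∇E) + α·ΔW_{t−1}`, apply it, and re-evaluate the total error
`E` (the sum of per-sample errors over the batch):

- `E` rose → the adjustment is invalid: weights are restored bit-for-bit,
  `η ← β·η`, and the momentum memory is cleared. An invalid step should
  not echo through the momentum term, so `ΔW_{t−1}` is zeroed rather than
  kept — keeping it would re-apply a rejected direction on the next epoch.
- `E` fell or was unchanged → the step stands and `η ← θ·η`.

Defaults `α = 0.9`, `β = 0.7`, `θ = 1.05` are the customary adaptive
gradient-descent values; `η₀ = 0.5` suits the mean-scaled gradient (see
below). All are configurable through `gd_control()`.

Internally the gradient is taken on the *mean* squared error over
samples × outputs rather than the raw sum, so that the default `η` does
not depend on the batch size; the two differ by a constant factor and
give identical trajectories after rescaling `η`. The error that the
adaptive rule, the stopping rule (`goal_error`) and the recorded history
use is the total error (sum of `E_p`), since its magnitude is what the
flat-area thresholds below are calibrated against.

### Flat-area handling

A plateau is declared when the epoch-to-epoch change in total error is
nearly zero (`|ΔE| < grad_tol`, default `1e-6`) while the largest output
residual `|d_k − o_k|` still exceeds `residual_tol` (default 0.1 — a
quarter of the 0.4 output range, clearly "not converged"). Then `λ` is
set to `lambda_boost` (default 4), de-saturating the neurons so the
gradient flows again; once `|ΔE|` exceeds the threshold, `λ` returns
to 1. Two loop details matter:

1. The rule is evaluated **only after accepted steps**. A rejected,
   rolled-back epoch leaves the error unchanged (`ΔE = 0` exactly), which
   says nothing about surface flatness; treating it as a plateau would
   fire the boost during ordinary learning-rate searching.
2. Best-so-far weights are always judged at the *operational* factor
   `λ = 1`. Objectives at boosted `λ` live on a different error surface
   and are not comparable; the model that is returned, saved and used
   for prediction always runs at `λ = 1`.

The flat-area device assumes that a persistently large residual signals
saturation. On noisy data the largest residual may never fall below
`residual_tol` even at genuine convergence, so the feature is part of the
GA+BP profile (where the total-error-scale `grad_tol` keeps it dormant
except on real plateaus) and off in the plain BP profile.

### Two named profiles

- `bp_improved`: tangent activation, momentum + adaptive `η`. The
  baseline improved-BP configuration with random initial weights.
- `gabp_paper`: logistic activation (the form the gradient factor is
  defined for), momentum + adaptive `η` + flat-area gradient factor,
  intended to be paired with GA-optimized initial weights.

## Normalization

Inputs are min–max scaled per dimension, fitted on the training split
only: to `[0.1, 0.9]` for the logistic activation and `[−1, 1]` for the
tangent activation, keeping inputs off the saturation asymptotes.
Outputs are left in raw mass-fraction units — they already lie in
`[0, 0.4]`, inside both activations' comfortable range — so predictions
are directly comparable to published actual-output examples, which do
not sum to 0.40. `predict(..., clip = TRUE)` optionally restores the
simplex for mixable recipes; it is off by default because errors are
scored on raw outputs.

## Error metrics

`E_p = Σ_k (d_k − o_k)²` per sample, and the aggregate
`E_MSE = (1/P) Σ_p E_p²` — note this squares `E_p`, which is itself
already a sum of squares. The package implements this as printed because
it is the form the method's published comparisons use; whether the inner
square is intentional cannot be resolved from the source material, so
the conventional mean of `E_p` is equally available
(`total_mse(errors, metric = "mean_ep")`) and every report states which
metric it used. All package-level comparisons default to the as-printed
form.

## The genetic algorithm

Chromosomes are the flattened network parameters in four segments
(input–hidden weights row-major, hidden–output weights row-major, hidden
thresholds, output thresholds); encode/decode is an exact bijection.
Fitness is `1/(E + ε)` with `ε = 1e-6`, strictly decreasing in the
training error `E`. Choices where the method description is open:

- **Fitness evaluation**: by default the *untrained* decoded network is
  scored (`static_error`) — the common GA-initialization reading, and
  cheap enough to run a 40-individual population for 50 generations in
  seconds. A `trained_error` mode first applies `k` gradient-descent
  epochs or `k` Levenberg–Marquardt iterations (default `k = 5`),
  reflecting the variant where the fitness function itself trains with
  LM. Both modes are exercised in the test suite.
- **Crossover**: single-point on the flat gene vector, exchanging the
  tail beyond a uniformly drawn cut; a segment-aligned variant (cut only
  at the four segment boundaries) is available.
- **Mutation**: per-gene uniform resampling from the gene range
  (default `[−1, 1]`), probability 0.05; a Gaussian-perturbation variant
  exists behind a flag.
- **Elitism**: 1 by default, which makes the per-generation best fitness
  monotone non-decreasing (a tested property); set 0 for a literal
  selection-only loop.
- Population 40, 50 generations, crossover probability 0.7: standard
  small-GA values, declared rather than inferred.

## Levenberg–Marquardt trainer

For small dense networks the full residual Jacobian (`P·5` rows × 113
columns at `h = 12`) is cheap, so a classic damped Gauss–Newton is
provided: solve `(JᵀJ + μI)δ = Jᵀr`, step `p ← p − δ`, accept and divide
`μ` by 10 when the SSE drops, reject and multiply by 10 otherwise
(`μ₀ = 1e-3`, ceiling `1e10`). The accepted-step SSE sequence is strictly
decreasing by construction, and the analytic Jacobian is verified against
finite differences; the whole solver is cross-checked against an
independent damped least-squares implementation in the test suite.

## Hidden-layer sizing

`h = √(n+m) + a` with integer `a ∈ [1, 10]`; rounding is half-up
(`⌊x + 0.5⌋`), which yields candidates 4–13 for `n = 3, m = 5`
(`√8 ≈ 2.83`). The trial-and-error sweep trains `reps` independently
seeded networks per candidate with otherwise identical parameters and
picks the smallest `h` minimizing the mean held-out `E_MSE`; a diverged
repetition is recorded as an infinite error, which removes its candidate
from contention. On the smooth synthetic surrogate the sweep often
prefers small `h` — the surrogate is easier than real fired-ceramic
optics, and the selected size should not be read as a statement about
real specimen data.

## The synthetic specimen generator

The real specimen database is unpublished, so the generator reproduces
its *structure*: recipes are uniform over the 126 weak compositions of
five 0.08 g increments summing to 0.40 g (every published example row
obeys this law; we state it as an assumption), and colors come from

    lab = offset + basisᵀ·recipe + curvature·g(recipe) + noise

with a fixed per-powder color basis, a fixed smooth quadratic
interaction `g` standing in for non-additive optical mixing, and
independent Gaussian noise per channel (`sd = 0.3` CIELAB units, a
typical intra-instrument repeatability; curvature 5, giving
order-half-unit nonlinear effects). The default pure-component colors
are fixed constants chosen so the generated ranges bracket the observed
specimen extremes (L* ≈ 63.9–72.5, a* ≈ −1.3–1.8, b* ≈ 14.6–21.6);
they are synthetic stand-ins, not measured optical constants.

Because every recipe sums to the same total, an additive color offset is
exactly collinear with a uniform shift of the basis — offset and basis
are not jointly identifiable from on-simplex data. The generator
therefore uses a zero offset with the baseline folded into the basis,
and `fit_linear_mixing()` fits the no-intercept linear map, which
recovers the basis to numerical precision on noiseless zero-curvature
data (a tested parameter-recovery property).

What the generator does **not** emulate: Kubelka–Munk radiative
transfer, firing-process variability, instrument metamerism, or any
correlation between recipe and measurement error. Tests passing on
synthetic data therefore demonstrate that the algorithms are implemented
correctly and that the GA initialization behaves as designed — not that
the trained networks meet clinical accuracy on real specimens.

## Reference experiment and problem sizes

The packaged reference experiment fixes the synthetic dataset (119
samples, default generator, seed 42; 75/25 split, seed 1) as the study
condition — the analogue of a fixed specimen database — and varies the
experiment's randomness (initializations, GA runs) on top. The
BP-vs-GA+BP comparison runs 10 independently seeded trainings per arm at
`h = 12` and reports per-trial held-out `E_MSE` with means and
variances; the hidden-node sweep uses 20 repetitions per candidate.
These sizes mirror the original experiment's shape (10 trials, 20
predictions per trial) and complete in about a minute on one CPU.

The end-to-end learnability gate trains GA+BP on 89 noiseless samples
and requires held-out `E_MSE` below `1e-3`. The threshold is the
one-grid-step criterion: a mean per-powder deviation of 0.08 (the recipe
grid spacing) gives `E_p = 5·0.08² = 0.032`, hence `E_MSE ≈ E_p² ≈ 1e-3`;
a model at the gate is accurate to within one powder increment on
average.

## Known limitations

- The comparison's direction (GA+BP mean and variance no worse than BP)
  is a property of the reference experiment, not a theorem; on easier
  synthetic datasets plain BP can match GA+BP's mean while GA+BP retains
  the lower variance.
- Raw predictions are unconstrained; physically mixable recipes require
  the clip-and-rescale post-processing, which is not error-optimal.
- The as-printed `E_MSE` squares already-squared quantities and is
  dominated by the worst samples; use `mean_ep` for a conventional view.
- No uncertainty quantification on predictions; seeds make runs
  reproducible but the package does not model prediction variance.
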