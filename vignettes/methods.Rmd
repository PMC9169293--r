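---
title: "Methods: unit-level small area estimation with boosted trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: unit-level small area estimation with boosted trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The estimation problem

Surveys of health, housing and well-being indicators reach a few percent of
a population; registry data (demographics, household attributes, home
coordinates) cover everyone. Unit-level small area estimation treats the
missing survey responses as a supervised prediction problem: fit
`f: features -> mean response` on the respondents, predict everyone else,
and average the combined observed/predicted responses `y*` over each region
of a nested geography (neighborhood ⊂ district ⊂ municipality). The region
estimate `p_r` is a plain mean, so estimates are exactly consistent across
levels, and a census (100% survey) reproduces raw means exactly.

The inferential target of the accompanying intervals is the **realized
finite-population mean** of the region — the prevalence the region actually
has this year — not a superpopulation parameter. Two consequences follow:
respondents' outcomes are *known* and must not be re-simulated (the
finite-sample correction), and interval width must tend to zero as survey
coverage tends to the census.

## Bootstrap prediction intervals

For `b = 1..B`: resample the `n` respondents with replacement, refit the
model (`f^(b)`), and simulate outcomes for the unsurveyed individuals only —
`Bernoulli(f^(b)(x_i))` for binary outcomes, `Normal(f^(b)(x_i), σ²)` for
ratings, independently across individuals — keeping surveyed outcomes at
their observed values. The percentiles of the `B` region means form the
interval. Model uncertainty enters through the refits; outcome uncertainty
through the simulation.

Numerical choices:

* `B = 200` by default. Percentile estimates at the 2.5/97.5% points are
  stable to ~1% of the interval width at this `B`; doubling `B` changes
  third decimals.
* Percentiles use linear interpolation between order statistics
  (`stats::quantile` type 7).
* For ratings, `σ² = (1/n) Σ (y_i − f̄(x_i))²` is computed **once** from the
  across-replicate mean prediction `f̄`, not per replicate: the residual
  variance is a property of the outcome model, and per-replicate versions
  only add noise.
* Rating simulations are *not* truncated to the rating scale; a bounded
  outcome model is deliberately out of scope, and region means essentially
  never leave the scale except in pathological settings.
* Binary predictions from adapter models are clamped to [0,1] with a
  warning (library boosters can overshoot in raw-score edge cases).
* For the library booster, the number of boosting rounds is selected by
  cross-validation **once**, on the original survey, and held fixed across
  the `B` refits (`gbt_lib_select_rounds`). Re-selecting per replicate is
  two orders of magnitude slower and adds selection noise without capturing
  any additional uncertainty of interest.

## When are the intervals calibrated? (design of the coverage study)

The bootstrap captures *estimation variance* — how `f` would change under a
different survey draw — but is blind to *estimation bias*. The package's
calibration study (`scripts/acceptance.R`, mirrored in the test suite)
therefore separates two questions:

1. **Is the interval machinery right?** An oracle predictor that returns
   the generator's true probabilities yields coverage at the nominal level,
   validating resampling, simulation and percentile logic.
2. **Is the procedure calibrated with a fitted model?** That holds when the
   classifier is *correctly specified* and estimable without systematic
   bias at the survey size. The study uses `piecewise_surface()` — strong
   discrete effects (sex, an education gradient, an age-65 step) plus a
   checkerboard spatial field — and fits a logistic GLM carrying exactly
   those terms through the predictor contract (`predictor_glm`). With
   ~2,000 respondents and a dozen parameters, maximum-likelihood
   estimation is effectively unbiased, the bootstrap reproduces its
   sampling distribution, and measured coverage sits at the nominal 95%
   (the acceptance script prints the number it measures).

A boosted-tree model at the same survey size is **not** correctly specified
in this estimation sense, even when the true surface is tree-representable:
shrinkage from the learning rate, early stopping, and split-boundary
localization error are all *bias*, invisible to resampling, and they push
empirical coverage below nominal. This is a property of pairing percentile
bootstrap with regularized learners, not an implementation artifact; it is
the reason the calibration study pairs the interval procedure with an
exactly specified classifier, while boosted models are evaluated on point
accuracy (validation module, small-area recovery) where their strength
lies. Users producing intervals from boosted fits on small surveys should
expect them to be somewhat anti-conservative.

## The reference boosting implementation

`boost()` implements stagewise gradient boosting with CART base learners:
start from the loss family's optimal constant; per round fit a regression
tree to the negative gradient at the current fit, set each leaf to the
loss family's terminal-node estimate, and add the tree scaled by the
learning rate `α`.

* Loss families: squared (gradient `y − f`, exact leaf mean) and logistic
  on the raw score (gradient `y − σ(f)`, one-step Newton leaf
  `Σ(y − p) / Σ p(1−p)` — the standard approximation to the terminal-node
  argmin; exact line search costs more than it buys).
* Split search: squared-error reduction over all candidates; continuous
  thresholds at midpoints between consecutive distinct values; categorical
  splits one-vs-rest by level (full subset search is exponential in
  levels and was rejected). Every candidate carries a learned
  missing-value direction, and an extra candidate isolates the missing
  group itself, so missingness acts as a splitting criterion and no
  imputation is required.
* Ties in gain break deterministically: lowest feature index, then lowest
  threshold.
* Defaults `α = 0.3, T = 50` (the unoptimized variant); the optimized
  variant uses `α = 0.1` with early stopping by 5-fold cross-validation —
  fold models grow in lockstep and the scan stops 10 rounds past the
  running minimum of mean held-out loss (the training loss family's own
  value). `max_depth = 6`, `min_leaf_size = 20` mirror common booster
  defaults; tree-level hyperparameters beyond `α` and `T` are deliberately
  few.
* No shrinkage on the constant `f0`; `α` applies from stage 1.
* Second-order split gains, leaf regularization and row/column subsampling
  are out of scope — they belong to the production booster
  (`predictor_gbt_lib`), which satisfies the same contract and agrees with
  the reference to within 10% held-out MSE on matched settings (asserted
  in the test suite).

## Oblique geographic coordinates

`ogc_transform` maps `(x, y)` to `K` projections
`x cos θ_k + y sin θ_k`, `θ_k = π(k−1)/K`. The equivalent polar form
`√(x²+y²)·cos(θ_k − atan(y/x))` is implemented with the two-argument
arctangent: for positive `x` (Dutch map coordinates are) the two coincide,
and `atan2` extends the formula to all quadrants; the origin maps to the
zero vector (the projection's limit). `K = 24` is the default; the raw
coordinates are *replaced* by the oblique features unless
`include_raw_xy = TRUE` — with all 24 projections the raw pair adds no
information a tree can use that `θ = 0` and `θ = π/2` do not already carry.

## Sequential imputation

For predictors that cannot accept missing values, `sequential_impute`
processes features in ascending order of missing fraction (ties broken by
column position): a random forest (100 trees, ranger) is trained on the
currently complete columns over rows where the feature is observed, and
predicts its missing entries — classification for factors, regression for
numerics. One sequential sweep, as the procedure is defined; no iteration
to convergence, no multiple imputation (uncertainty propagation through
imputation is a non-goal). Observed entries are never altered, the result
is idempotent, and coordinates are never imputed (they are complete by
construction).

## The synthetic population generator

The generator exists because the registry microdata such studies run on
are access-restricted. It emulates their statistical structure:

* **Schema** (`default_feature_schema`): individual demographics (age,
  sex, 7-level ethnicity, marital status, 8-level education), household
  variables (type, size, income source, home ownership, income/asset
  percentiles), neighborhood address density. Missingness is missing
  completely at random per feature, with education at the registry's
  characteristic 37.8% and income-related features near 2.4%.
* **Geography**: neighborhoods tile the 50 × 50 km extent on a grid
  (row-major, so consecutive codes are adjacent), nest in districts and
  municipalities (defaults 4 × 5 × 5 = 100 neighborhoods), and receive
  gamma-weighted random populations so sizes vary realistically — small
  neighborhoods with < 15 respondents arise naturally at a 10% survey.
  Individuals draw uniform coordinates within their neighborhood tile,
  giving the location–region correlation spatial modeling presumes.
* **Outcome surfaces**: `default_surface()` is a smooth logistic surface
  (~30% prevalence) with a nonlinear age profile, demographic and
  education effects, an income slope, an age-by-sex interaction and a
  sinusoidal spatial field — the structure flexible learners are meant to
  capture. `piecewise_surface()` is its discrete counterpart for
  calibration studies (see above). Surfaces are evaluated on the
  *complete* features before missingness is applied.
* **Survey designs**: independent (Poisson) inclusion at a configured
  fraction; optionally tilted monotonically by a named feature
  (`bias_feature`, e.g. income) to emulate non-representative response,
  and optionally per-municipality fractions approximating stratification.

What the generator does **not** emulate: real geography or map
projections, household-level clustering of individuals, spatially
clustered demographics (features are drawn independently of location), and
any actual survey's stratification weights. Passing tests therefore
demonstrate the estimator's properties under its stated assumptions — not
performance on any particular real registry.

## Problem sizes used in the shipped studies

The packaged studies run at 20,000 individuals / 100 neighborhoods / 10%
surveys with `B = 200` and 10 simulation replicates — large enough that
binomial noise does not dominate neighborhood means (~200 individuals
each), small enough for interactive runs. The bias-correction study uses
20 survey replicates on one fixed population; the recovery study compares
model-based and direct estimators among neighborhoods with fewer than 15
respondents, where direct estimation degrades fastest.

## Known limitations

* Intervals from regularized learners (boosting included) under-cover to
  the extent the learner is biased at the survey size; see the coverage
  discussion above.
* Bootstrap resampling is uniform over respondents; survey design weights
  and post-stratification are out of scope by design.
* The direct estimator is undefined (NA) in regions with zero
  respondents; the model-based estimator covers them, which is the point
  of the method.
* Rating outcomes use an unbounded normal model; scales with strong floor
  or ceiling effects are approximated, not modeled.
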