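# saeboost

Unit-level small area estimation (SAE) with gradient boosted trees and
model-agnostic bootstrap prediction intervals.

Local policymakers need prevalences of health indicators — or average
housing-satisfaction ratings — for neighborhoods where a survey may have a
handful of respondents, or none. Directly averaging survey responses per
neighborhood (the *direct estimator*) is then unusable. Unit-level SAE
borrows strength from registry data covering the whole population: a
predictive model is trained on respondents (features: demographics,
household variables, coordinates), the unsurveyed individuals' responses
are predicted, and the combined responses are averaged over any nested
geography.

## The estimator

For a population `[N]` with survey subset `I` of size `n`, features `x_i`
and responses `y_i` (binary indicator or real rating, observed only on
`I`), a model `f` fitted on `{(x_i, y_i) : i ∈ I}` defines the combined
response

    y*_i = y_i        if i ∈ I
           f(x_i)     otherwise

and the estimate for region `R_r` is the plain average
`p_r = (1/|R_r|) Σ_{i ∈ R_r} y*_i`. Because every individual enters exactly
one region per level, estimates aggregate exactly: a district estimate is
the population-weighted mean of its neighborhoods'.

Uncertainty is quantified by a model-agnostic bootstrap: for `b = 1..B`
resample the respondents, refit `f^(b)`, and simulate a full-population
outcome vector — `y_i^(b) ~ Bernoulli(f^(b)(x_i))` for binary outcomes, or
`Normal(f^(b)(x_i), σ²)` with `σ² = (1/n) Σ_{i∈I} (y_i − f̄(x_i))²` for
ratings — while respondents keep their observed `y_i` (a finite-sample
correction: intervals shrink to zero width as the survey approaches a
census). The empirical 2.5/97.5 percentiles of the `B` simulated region
means are the 95% prediction interval for the realized region mean.

The model is pluggable (`sae_predictor` contract). Included:

* `predictor_null()` — the survey mean everywhere (baseline);
* `predictor_gbt_ref()` — a from-scratch reference implementation of
  gradient boosted CART trees with learned missing-value split directions
  and 5-fold-CV early stopping;
* `predictor_gbt_lib()` — the same contract backed by the xgboost library
  for production-scale runs;
* `predictor_glm()` — formula-based (G)LMs as comparator models.

Spatial signal can enter as raw x/y coordinates or as K = 24 *oblique
geographic coordinates* (`ogc_transform`): projections
`x cos θ_k + y sin θ_k`, `θ_k = π(k−1)/K`, which give axis-aligned tree
splits access to oblique boundaries. A sequential random-forest imputation
(`sequential_impute`) serves models that cannot accept missing values,
filling features from least- to most-missing.

Because the registry microdata such a study runs on are access-restricted,
the package ships a synthetic population generator
(`generate_population`) that emulates their structure — categorical
demographics with realistic missingness (education 37.8% missing),
household variables, neighborhood → district → municipality nesting,
coordinates correlated with neighborhoods, and a known outcome surface
with nonlinearities, interactions and a smooth spatial field — so every
claim the package makes is testable against a known truth.

## Worked example

```r
library(saeboost)

pc  <- population_config(n_individuals = 20000, seed = 42)   # 100 neighborhoods
pop <- generate_population(pc)                               # known logistic surface
svy <- sample_survey(pop$frame, survey_design(sampling_fraction = 0.1, seed = 42))

X <- build_design(svy, spatial_mode = "ogc", ogc_config(24), encoding = "indicator")
s <- svy$survey_flag == 1

# out-of-sample validation, boosted trees vs null model
oos <- kfold_oos_predictions(X[s, ], svy$response[s],
                             predictor_gbt_lib("logistic", 0.1, 100, 3),
                             k = 5, seed = 42)
compute_metrics(svy$response[s], oos$predictions)
#> n=1951  accuracy=0.7166  AUC=0.6087  MSE=0.1983  NLL=0.5865

# region estimates with 95% bootstrap prediction intervals
est <- bootstrap_prediction_intervals(svy, X,
         predictor_gbt_lib("logistic", 0.1, 100, 3),
         level = "neighborhood", n_replicates = 200, seed = 42)
head(est[, c("region_code", "n_population", "n_respondents",
             "estimate", "lower", "upper")], 4)
#>   region_code n_population n_respondents estimate  lower upper
#> 1      NB0001           44             5    0.240 0.0682 0.386
#> 2      NB0002          158            13    0.230 0.1328 0.374
#> 3      NB0003          136             9    0.280 0.1691 0.390
#> 4      NB0004          390            45    0.278 0.2101 0.364
```

The boosted model improves out-of-sample Brier score over the null model
(0.1983 vs 0.2001) and discriminates (AUC 0.61 vs 0.46) on this synthetic
indicator. The payoff is at small-area level: against the generator's true
neighborhood means, the model-based estimates reach RMSE 0.049 where the
direct respondent-only estimator attains 0.161 (with ~20 respondents per
neighborhood on average, and many neighborhoods far below that). Intervals
are widest where the surveyed share is smallest (NB0001: 5 of 44).

A command-line wrapper over the same functions is installed at
`inst/cli/saeboost.R` with subcommands `simulate`, `transform`, `fit`,
`estimate`, `validate`, `run`:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "saeboost.R", package = "saeboost"))') \
  run --config run.yaml --seed 1
```

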