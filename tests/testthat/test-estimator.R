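# Combined responses, region aggregation, direct estimator, bootstrap
# percentile prediction intervals.

test_that("null model predicts the survey mean for everyone", {
  fit <- fit_null(c(1, 1, 0, 1))
  expect_equal(predict(fit, data.frame(x = 1:7)), rep(0.75, 7))
  fitr <- fit_null(c(7.0, 8.0))
  expect_equal(predict(fitr, data.frame(x = 1:3)), rep(7.5, 3))
  expect_error(fit_null(numeric(0)), "empty")
  # every region receives the same estimate
  f <- toy_frame()
  X <- build_design(f, "xy")
  s <- f$survey_flag == 1
  fitted <- fit_predictor(predictor_null(), X[s, ], f$response[s])
  ystar <- combine_predicted_responses(f, fitted, X)
  est <- aggregate_regions(ystar, f, "district")
  expect_equal(length(unique(round(est$estimate - est$estimate[1], 12))), 1L)
})

test_that("y* is observed for respondents, prediction otherwise", {
  f <- toy_frame()
  X <- build_design(f, "xy")
  fitted <- fit_predictor(constant_predictor(0.3), X, numeric(1))
  ystar <- combine_predicted_responses(f, fitted, X)
  s <- f$survey_flag == 1
  expect_identical(ystar[s], f$response[s])
  expect_true(all(ystar[!s] == 0.3))
  # full census: y* identical to the observed response vector
  census <- f
  census$survey_flag <- 1L
  census$response <- ifelse(is.na(census$response), 0, census$response)
  expect_identical(combine_predicted_responses(census, fitted, X),
                   census$response)
})

test_that("unscorable unsurveyed rows error with the row id", {
  f <- toy_frame()
  X <- build_design(f, "xy")
  napred <- new_predictor("na", fit = function(X, y) NULL,
                          predict_fun = function(ft, X) rep(NA_real_, nrow(X)))
  fitted <- fit_predictor(napred, X, 1)
  expect_error(combine_predicted_responses(f, fitted, X), "could not score")
})

test_that("region aggregation: counts, means, weighted nesting", {
  f <- toy_frame()
  ystar <- c(1, 0, 1, 1, 1, 0, 0, 1, 1, 1)
  nb <- aggregate_regions(ystar, f, "neighborhood")
  expect_equal(nb$estimate[nb$region_code == "NB01"], 0.75)
  expect_equal(nb$n_population, c(4L, 2L, 3L, 1L))
  expect_equal(nb$n_respondents, c(2L, 1L, 2L, 1L))
  # district estimate is the population-weighted mean of its neighborhoods
  di <- aggregate_regions(ystar, f, "district")
  w <- (4 * 0.75 + 2 * nb$estimate[nb$region_code == "NB02"]) / 6
  expect_equal(di$estimate[di$region_code == "DI1"], w)
  # national estimate equals the overall mean of y*
  nat <- aggregate_regions(ystar, f, "national")
  expect_equal(nat$estimate, mean(ystar))
  # conservation at every level
  for (lv in c("neighborhood", "district", "municipality")) {
    e <- aggregate_regions(ystar, f, lv)
    expect_equal(sum(e$n_population * e$estimate) / sum(e$n_population),
                 mean(ystar))
  }
})

test_that("direct estimator is NA for regions without respondents", {
  f <- toy_frame()
  f$survey_flag[f$region_nbhd == "NB02"] <- 0L
  f$response[f$region_nbhd == "NB02"] <- NA
  d <- direct_estimates(f, "neighborhood")
  expect_true(is.na(d$estimate[d$region_code == "NB02"]))
  expect_equal(d$estimate[d$region_code == "NB01"], 0.5)
})

test_that("residual variance follows the plug-in formula", {
  expect_equal(residual_variance(c(0, 2), c(1, 1)), 1)
  expect_equal(residual_variance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(residual_variance(c(0, 2, 5), c(1, 1, 4)),
               residual_variance(c(5, 0, 2), c(4, 1, 1)))
  expect_error(residual_variance(numeric(0), numeric(0)), "no respondents")
})

test_that("full-census survey gives zero-width intervals", {
  pop <- generate_population(small_config(n = 400L, seed = 41L))
  census <- pop$frame           # generated as a census
  X <- build_design(census, "xy")
  est <- bootstrap_prediction_intervals(census, X, predictor_null(),
                                        n_replicates = 25L, seed = 3L)
  expect_equal(est$lower, est$estimate, tolerance = 1e-12)
  expect_equal(est$upper, est$estimate, tolerance = 1e-12)
})

test_that("B=1 collapses the interval to the single replicate", {
  pop <- generate_population(small_config(n = 400L, seed = 43L))
  sv <- sample_survey(pop$frame, survey_design(0.5, seed = 5L))
  X <- build_design(sv, "xy")
  est <- bootstrap_prediction_intervals(sv, X, predictor_null(),
                                        n_replicates = 1L, seed = 7L)
  expect_identical(est$lower, est$upper)
})

test_that("binary bounds and estimates lie in [0,1]; widths shrink with coverage", {
  pop <- generate_population(small_config(n = 2000L, seed = 47L))
  X <- build_design(pop$frame, "xy")
  widths <- sapply(c(0.1, 0.5, 0.9), function(fr) {
    sv <- sample_survey(pop$frame, survey_design(fr, seed = 9L))
    est <- bootstrap_prediction_intervals(sv, X, predictor_null(),
                                          n_replicates = 60L, seed = 11L)
    expect_true(all(est$estimate >= 0 & est$estimate <= 1))
    expect_true(all(est$lower >= 0 & est$upper <= 1))
    expect_true(all(est$lower <= est$upper))
    mean(est$upper - est$lower)
  })
  expect_true(all(diff(widths) < 0))
})

test_that("continuous outcomes simulate with the pooled residual variance", {
  sf <- true_surface(link = "identity", intercept = 7, noise_sd = 1)
  pop <- generate_population(small_config(n = 1000L, seed = 53L), sf)
  sv <- sample_survey(pop$frame, survey_design(0.3, seed = 13L))
  X <- build_design(sv, "xy")
  est <- bootstrap_prediction_intervals(sv, X, predictor_null(),
                                        outcome = "continuous",
                                        n_replicates = 80L, seed = 17L)
  s2 <- attr(est, "sigma2")
  expect_gt(s2, 0.8); expect_lt(s2, 1.25)   # recovers noise_sd^2 = 1
  expect_true(all(est$upper > est$lower))
})

test_that("model-based estimator beats the direct one in small areas", {
  pop <- generate_population(population_config(n_individuals = 20000L, seed = 59L))
  sv <- sample_survey(pop$frame, survey_design(0.1, seed = 19L))
  X <- build_design(sv, "ogc", ogc_config(24), encoding = "indicator")
  s <- sv$survey_flag == 1
  fitted <- fit_predictor(predictor_gbt_lib("logistic", 0.1, 100L, 3L),
                          X[s, ], sv$response[s])
  ystar <- combine_predicted_responses(sv, fitted, X)
  model_est <- aggregate_regions(ystar, sv, "neighborhood")
  direct <- direct_estimates(sv, "neighborhood")
  tm <- true_region_means(pop$true_means, pop$frame, "neighborhood")
  small <- model_est$n_respondents < 15
  truth <- tm$true_mean[match(model_est$region_code, tm$region_code)]
  dir_est <- direct$estimate[match(model_est$region_code, direct$region_code)]
  keep <- small & !is.na(dir_est)
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  expect_lt(rmse(model_est$estimate[keep], truth[keep]),
            rmse(dir_est[keep], truth[keep]))
})

test_that("model-based national estimate corrects income-biased sampling", {
  pop <- generate_population(population_config(n_individuals = 20000L, seed = 61L))
  X <- build_design(pop$frame, "ogc", ogc_config(24), encoding = "indicator")
  truth <- mean(pop$frame$response)
  wins <- 0L
  for (r in 1:20) {
    sv <- sample_survey(pop$frame, survey_design(
      0.1, bias_feature = "income_pct", bias_strength = 0.6,
      seed = derive_seed(23L, "bias-rep", r)))
    s <- sv$survey_flag == 1
    raw <- mean(sv$response[s])
    fitted <- fit_predictor(predictor_gbt_lib("logistic", 0.1, 100L, 3L),
                            X[s, ], sv$response[s])
    ystar <- combine_predicted_responses(sv, fitted, X)
    model_nat <- mean(ystar)
    if (abs(model_nat - truth) < abs(raw - truth)) wins <- wins + 1L
  }
  expect_gte(wins, 18L)
})
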