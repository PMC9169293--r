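# Cross-validated predictions, metrics, ROC/calibration curves, and
# region-estimate comparison.

test_that("k-fold assignment is a balanced partition; null OOS predictions
           equal training-fold means", {
  set.seed(71)
  X <- data.frame(a = rnorm(10))
  y <- rbinom(10, 1, 0.5)
  res <- kfold_oos_predictions(X, y, predictor_null(), k = 5L, seed = 3L)
  expect_equal(sort(unique(res$fold)), 1:5)
  expect_true(all(table(res$fold) == 2L))
  for (i in 1:5)
    expect_equal(unique(res$predictions[res$fold == i]), mean(y[res$fold != i]))
  expect_error(kfold_oos_predictions(X, y, predictor_null(), k = 1L), "k must")
  expect_error(kfold_oos_predictions(X[1:3, , drop = FALSE], y[1:3],
                                     predictor_null(), k = 5L), "fewer")
})

test_that("metrics match hand-computed oracle values", {
  # labels (1,1,1,1,0) at constant 0.8: mse = (4*0.04 + 0.64)/5 = 0.16
  m <- compute_metrics(c(1, 1, 1, 1, 0), rep(0.8, 5))
  expect_equal(m$mse, 0.16, tolerance = 1e-12)
  expect_equal(m$nll, -(4 * log(0.8) + log(0.2)) / 5, tolerance = 1e-12)
  expect_equal(m$nll, 0.5004, tolerance = 1e-4)
  expect_equal(m$accuracy, 0.8)
  # auc on (1,0,1) vs (0.9, 0.5, 0.4): one concordant, one discordant pair
  m2 <- compute_metrics(c(1, 0, 1), c(0.9, 0.5, 0.4))
  expect_equal(m2$auc, 0.5)
  # perfect predictions
  m3 <- compute_metrics(c(1, 0, 1, 0), c(1, 0, 1, 0))
  expect_equal(m3$mse, 0); expect_equal(m3$accuracy, 1); expect_equal(m3$auc, 1)
  expect_error(compute_metrics(c(1, 0), c(1.2, 0.5)), "\\[0, 1\\]")
})

test_that("pairwise AUC equals brute-force enumeration on random instances", {
  brute_auc <- function(y, p) {
    pos <- p[y == 1]; neg <- p[y == 0]
    s <- 0
    for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
    s / (length(pos) * length(neg))
  }
  for (seed in 1:5) {
    set.seed(seed)
    y <- rbinom(50, 1, 0.4)
    p <- round(runif(50), 2)   # rounding forces ties
    if (length(unique(y)) < 2) next
    expect_equal(compute_metrics(y, p)$auc, brute_auc(y, p))
  }
})

test_that("null-model metrics are internally consistent with prevalence", {
  # at prevalence a, constant-a predictions give accuracy a (a > 0.5),
  # Brier a(1-a), NLL -[a log a + (1-a) log(1-a)]: the published null row
  # accuracy 0.801 / AUC 0.5 / MSE 0.160 / NLL 0.500 is this identity
  a <- 0.801
  set.seed(77)
  y <- c(rep(1, 801), rep(0, 199))
  m <- compute_metrics(y, rep(a, 1000))
  expect_equal(m$accuracy, a)
  expect_equal(m$mse, a * (1 - a), tolerance = 1e-12)
  expect_equal(m$mse, 0.160, tolerance = 5e-3)
  expect_equal(m$nll, -(a * log(a) + (1 - a) * log(1 - a)), tolerance = 1e-12)
  expect_equal(m$nll, 0.500, tolerance = 5e-3)
  expect_true(is.na(m$auc) || abs(m$auc - 0.5) < 1e-12)
})

test_that("metrics are invariant to row permutation", {
  set.seed(79)
  y <- rbinom(100, 1, 0.5)
  p <- runif(100)
  o <- sample(100)
  m1 <- compute_metrics(y, p)
  m2 <- compute_metrics(y[o], p[o])
  expect_equal(m1[c("accuracy", "auc", "mse", "nll")],
               m2[c("accuracy", "auc", "mse", "nll")])
})

test_that("ROC endpoints, monotonicity, and trapezoid-vs-pairwise agreement", {
  set.seed(83)
  y <- rbinom(1000, 1, 0.45)
  p <- plogis(qlogis(0.45) + 1.5 * (y - 0.45) + rnorm(1000))
  roc <- roc_points(y, p, 100L)
  expect_true(all(roc$fpr >= 0 & roc$fpr <= 1 & roc$tpr >= 0 & roc$tpr <= 1))
  expect_true(all(diff(roc$fpr) <= 1e-12) && all(diff(roc$tpr) <= 1e-12))
  # trapezoid area under the 100-point curve close to pairwise AUC
  o <- order(roc$fpr)
  area <- sum(diff(roc$fpr[o]) * (head(roc$tpr[o], -1) + tail(roc$tpr[o], -1)) / 2)
  expect_lt(abs(area - compute_metrics(y, p)$auc), 0.02)
  # separable predictions attain the perfect corner
  ys <- c(rep(0, 5), rep(1, 5))
  ps <- c(rep(0.1, 5), rep(0.9, 5))
  rs <- roc_points(ys, ps, 100L)
  expect_true(any(rs$fpr == 0 & rs$tpr == 1))
  # constant predictions: only the two trivial corners
  rc <- roc_points(ys, rep(0.5, 10), 100L)
  expect_true(all((rc$fpr == 0 & rc$tpr == 0) | (rc$fpr == 1 & rc$tpr == 1)))
  expect_error(roc_points(rep(1, 5), runif(5)), "one class")
})

test_that("calibration bins: tie merging, partition, rank invariance", {
  # constant predictions collapse to a single merged bin
  y <- rep(c(0, 1), 25)
  cb <- calibration_bins(y, rep(0.5, 50), 10L)
  expect_equal(nrow(cb), 1L)
  expect_equal(cb$mean_predicted, 0.5)
  expect_equal(cb$observed_fraction, 0.5)
  # bins partition the sample
  set.seed(89)
  p <- runif(200)
  yy <- rbinom(200, 1, p)
  cb2 <- calibration_bins(yy, p, 20L)
  expect_equal(sum(cb2$n), 200L)
  # monotone transform preserves membership (same bin counts)
  cb3 <- calibration_bins(yy, p^3, 20L)
  expect_equal(cb2$n, cb3$n)
  expect_warning(calibration_bins(c(0, 1), c(0.2, 0.8), 10L), "reduced")
})

test_that("calibrated predictions track observed fractions at scale", {
  pop <- generate_population(small_config(n = 50000L, seed = 97L))
  mu <- pop$true_means
  y <- pop$frame$response
  cb <- calibration_bins(y, mu, 100L)
  dev <- cb$mean_predicted - cb$observed_fraction
  # per-bin binomial bound: deviations within 4 standard errors, and small
  # on average (mean |dev| ~ 0.8 * se for well-calibrated predictions)
  se <- sqrt(pmax(cb$mean_predicted * (1 - cb$mean_predicted), 1e-6) / cb$n)
  expect_lt(max(abs(dev) / se), 4)
  expect_lt(mean(abs(dev)), 0.05)
})

test_that("region comparison: correlation, difference bins, size strata", {
  est <- data.frame(region_code = sprintf("R%02d", 1:40),
                    estimate = seq(0.2, 0.6, length.out = 40),
                    n_population = rep(c(50L, 500L), 20))
  same <- compare_region_estimates(est, est)
  expect_equal(same$pearson, 1)
  expect_equal(same$diff_table$pct_regions[1], 100)
  shifted <- est
  shifted$estimate <- est$estimate + 0.03
  sh <- compare_region_estimates(est, shifted)
  expect_equal(sh$diff_table$pct_regions[2], 100)
  expect_equal(sh$diff_table$bin_lower[1:5], c(0, 0.025, 0.05, 0.075, 0.1))
  expect_equal(sh$diff_table$bin_upper[1:5], c(0.025, 0.05, 0.075, 0.1, 0.125))
  other <- est[-1, ]
  expect_error(compare_region_estimates(est, other), "differ")
  # size-stratified MSE with individual-level inputs
  set.seed(3)
  region <- sample(est$region_code, 500, replace = TRUE)
  labels <- rbinom(500, 1, 0.4)
  preds <- runif(500)
  cmp <- compare_region_estimates(est, est, labels = labels,
                                  predictions = preds, region = region,
                                  n_size_quantiles = 4L)
  expect_equal(sum(cmp$mse_by_size$n), 500L)
  expect_equal(nrow(cmp$mse_by_size), 4L)
})

test_that("fitted models beat the null model out of sample on real signal", {
  pop <- generate_population(small_config(n = 50000L, seed = 101L))
  sv <- sample_survey(pop$frame, survey_design(0.1, seed = 29L))
  s <- sv$survey_flag == 1
  X <- build_design(sv, "ogc", ogc_config(24), encoding = "indicator")[s, ]
  y <- sv$response[s]
  oos_gbt <- kfold_oos_predictions(X, y, predictor_gbt_lib("logistic", 0.1, 100L, 3L),
                                   k = 5L, seed = 31L)
  oos_null <- kfold_oos_predictions(X, y, predictor_null(), k = 5L, seed = 31L)
  mse_gbt <- compute_metrics(y, oos_gbt$predictions)$mse
  mse_null <- compute_metrics(y, oos_null$predictions)$mse
  expect_lt(mse_gbt, mse_null)
})
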