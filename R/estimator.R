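# Core estimator: combine observed and predicted responses into y*, average
# over nested regions, and attach model-agnostic bootstrap percentile
# prediction intervals with a finite-sample correction (respondents' observed
# outcomes stay fixed during outcome simulation, so intervals shrink to zero
# width as survey coverage approaches the census).

#' Combine observed and predicted responses (y*)
#'
#' For surveyed individuals y* is the observed response verbatim; for the
#' rest it is the fitted model's mean prediction (a probability, not a hard
#' label, for binary outcomes).
#'
#' @param frame population frame with `survey_flag` and `response`.
#' @param fitted a `sae_fitted` model (see [fit_predictor()]).
#' @param X design table for the whole population, row order matching
#'   `frame` (see [build_design()]).
#' @return numeric vector y* with no missing entries.
#' @export
combine_predicted_responses <- function(frame, fitted, X) {
  stopifnot(nrow(frame) == nrow(X))
  surveyed <- frame$survey_flag == 1L
  ystar <- frame$response
  if (any(surveyed & is.na(ystar)))
    stop("respondent row(s) with missing response: ",
         paste(utils::head(frame$id[surveyed & is.na(ystar)], 5), collapse = ", "))
  if (any(!surveyed)) {
    pred <- predict(fitted, X[!surveyed, , drop = FALSE])
    if (anyNA(pred)) {
      bad <- frame$id[!surveyed][is.na(pred)]
      stop("model could not score unsurveyed row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
    ystar[!surveyed] <- pred
  }
  ystar
}

#' Aggregate combined responses to region point estimates
#'
#' The estimate for region r is the arithmetic mean of y* over all its
#' individuals, `p_r = (1/|R_r|) sum_{i in R_r} y*_i`, so estimates are
#' exactly population-weighted-consistent across the nested levels.
#'
#' @param ystar combined responses from [combine_predicted_responses()].
#' @param frame population frame with region codes and `survey_flag`.
#' @param level `"neighborhood"`, `"district"`, `"municipality"` or
#'   `"national"`.
#' @param nominal_level nominal coverage recorded in the output (bounds are
#'   filled by [bootstrap_prediction_intervals()]).
#' @return data.frame with columns `level`, `region_code`, `n_population`,
#'   `n_respondents`, `estimate`, `lower`, `upper`, `nominal_level`.
#' @export
aggregate_regions <- function(ystar, frame, level = "neighborhood",
                              nominal_level = 0.95) {
  if (length(ystar) != nrow(frame)) stop("ystar length must match frame")
  if (anyNA(ystar)) stop("ystar must have no missing entries")
  col <- region_column(level)
  g <- if (is.null(col)) rep("ALL", nrow(frame)) else frame[[col]]
  if (anyNA(g)) stop("individual(s) with no region code at level ", level)
  g <- factor(g)
  est <- tapply(ystar, g, mean)
  npop <- tapply(rep(1L, length(g)), g, sum)
  nresp <- tapply(frame$survey_flag, g, sum)
  out <- data.frame(
    level = level,
    region_code = levels(g),
    n_population = as.integer(npop),
    n_respondents = as.integer(nresp),
    estimate = as.numeric(est),
    lower = NA_real_, upper = NA_real_,
    nominal_level = nominal_level,
    stringsAsFactors = FALSE
  )
  out[order(out$region_code), , drop = FALSE]
}

#' Direct (respondent-only) region estimates
#'
#' The classical raw estimator: the mean observed response among respondents
#' in each region. Regions with zero respondents get a missing estimate —
#' the failure mode small area estimation exists to address.
#'
#' @inheritParams aggregate_regions
#' @return data.frame as in [aggregate_regions()]; `estimate` is `NA` where
#'   `n_respondents` is 0.
#' @export
direct_estimates <- function(frame, level = "neighborhood") {
  col <- region_column(level)
  g <- if (is.null(col)) rep("ALL", nrow(frame)) else frame[[col]]
  g <- factor(g)
  surveyed <- frame$survey_flag == 1L
  est <- tapply(ifelse(surveyed, frame$response, NA_real_), g,
                function(v) mean(v, na.rm = TRUE))
  est[!is.finite(est)] <- NA_real_
  data.frame(
    level = level,
    region_code = levels(g),
    n_population = as.integer(table(g)),
    n_respondents = as.integer(tapply(frame$survey_flag, g, sum)),
    estimate = as.numeric(est),
    lower = NA_real_, upper = NA_real_, nominal_level = NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Residual variance from across-replicate mean predictions
#'
#' For continuous outcomes the simulation variance is estimated once from
#' the respondents as `sigma^2 = (1/|I|) sum (y_i - fbar(x_i))^2`, with
#' `fbar` the mean prediction across bootstrap replicates.
#'
#' @param y observed respondent responses.
#' @param fbar across-replicate mean prediction per respondent.
#' @return sigma-squared (scalar).
#' @export
residual_variance <- function(y, fbar) {
  if (length(y) == 0L) stop("no respondents")
  stopifnot(length(y) == length(fbar))
  mean((y - fbar)^2)
}

#' Bootstrap percentile prediction intervals for region estimates
#'
#' For each replicate b the respondents are resampled with replacement
#' (size n), the model is refitted, and a full-population outcome vector is
#' simulated: unsurveyed outcomes are drawn `Bernoulli(f_b(x_i))` (binary)
#' or `Normal(f_b(x_i), sigma^2)` (continuous, sigma^2 from
#' [residual_variance()]), independently across individuals, while surveyed
#' outcomes stay fixed at their observed values (finite-sample correction).
#' Region means of the simulated vectors give B bootstrap statistics per
#' region; the empirical `(1 - level)/2` and `(1 + level)/2` percentiles
#' (linear interpolation between order statistics) are the interval bounds.
#'
#' Continuous simulation draws are not truncated to any rating scale; in
#' near-degenerate settings a region mean can leave the scale and is
#' reported as computed.
#'
#' @param frame population frame (`survey_flag`, `response`, region codes).
#' @param X design table for the whole population (rows match `frame`).
#' @param predictor a `sae_predictor` (refitted on every replicate).
#' @param level region level, as in [aggregate_regions()].
#' @param outcome `"binary"` or `"continuous"`.
#' @param n_replicates number of bootstrap replicates B.
#' @param nominal_level interval coverage level in (0, 1).
#' @param seed integer seed (resampling and outcome simulation).
#' @param point_fitted optionally the already-fitted point model, used for
#'   the `estimate` column; fitted fresh if omitted.
#' @return [aggregate_regions()] table with `lower`/`upper` filled.
#' @export
bootstrap_prediction_intervals <- function(frame, X, predictor,
                                           level = "neighborhood",
                                           outcome = c("binary", "continuous"),
                                           n_replicates = 200L,
                                           nominal_level = 0.95,
                                           seed = 1L,
                                           point_fitted = NULL) {
  outcome <- match.arg(outcome)
  B <- as.integer(n_replicates)
  if (B < 1L) stop("n_replicates must be >= 1")
  if (nominal_level <= 0 || nominal_level >= 1) stop("nominal_level must be in (0,1)")
  surveyed <- which(frame$survey_flag == 1L)
  n <- length(surveyed)
  if (n < 2L) stop("need at least 2 respondents to bootstrap")
  unsurveyed <- which(frame$survey_flag == 0L)
  y_obs <- frame$response[surveyed]

  if (is.null(point_fitted))
    point_fitted <- fit_predictor(predictor, X[surveyed, , drop = FALSE], y_obs)
  ystar <- combine_predicted_responses(frame, point_fitted, X)
  est <- aggregate_regions(ystar, frame, level, nominal_level)

  col <- region_column(level)
  g <- factor(if (is.null(col)) rep("ALL", nrow(frame)) else frame[[col]],
              levels = est$region_code)
  npop <- est$n_population

  # fit all replicate models first; predictions for respondents are needed
  # across replicates before simulation in the continuous case (fbar, sigma^2)
  set.seed(derive_seed(seed, "bootstrap"))
  fits_pred_pop <- matrix(NA_real_, length(unsurveyed), B)
  fits_pred_resp <- if (outcome == "continuous") matrix(NA_real_, n, B) else NULL
  for (b in seq_len(B)) {
    take <- sample.int(n, n, replace = TRUE)
    fb <- fit_predictor(predictor, X[surveyed[take], , drop = FALSE], y_obs[take])
    if (length(unsurveyed)) {
      pb <- predict(fb, X[unsurveyed, , drop = FALSE])
      if (outcome == "binary") pb <- clamp01(pb)
      fits_pred_pop[, b] <- pb
    }
    if (outcome == "continuous")
      fits_pred_resp[, b] <- predict(fb, X[surveyed, , drop = FALSE])
  }
  sigma2 <- if (outcome == "continuous")
    residual_variance(y_obs, rowMeans(fits_pred_resp)) else NULL

  # simulate outcomes and aggregate; surveyed outcomes stay observed
  region_sums_fixed <- tapply(
    ifelse(frame$survey_flag == 1L, frame$response, 0), g, sum)
  region_sums_fixed[is.na(region_sums_fixed)] <- 0
  g_un <- g[unsurveyed]
  p_mat <- matrix(NA_real_, length(est$region_code), B)
  for (b in seq_len(B)) {
    if (length(unsurveyed)) {
      mu_b <- fits_pred_pop[, b]
      y_b <- if (outcome == "binary") stats::rbinom(length(mu_b), 1L, mu_b)
             else stats::rnorm(length(mu_b), mu_b, sqrt(sigma2))
      sums <- tapply(y_b, g_un, sum)
      sums[is.na(sums)] <- 0
      add <- rep(0, length(levels(g)))
      names(add) <- levels(g)
      add[names(sums)] <- sums
    } else add <- rep(0, length(levels(g)))
    p_mat[, b] <- (as.numeric(region_sums_fixed) + add) / npop
  }

  alpha <- (1 - nominal_level) / 2
  est$lower <- apply(p_mat, 1, stats::quantile, probs = alpha, names = FALSE)
  est$upper <- apply(p_mat, 1, stats::quantile, probs = 1 - alpha, names = FALSE)
  if (outcome == "binary") {
    est$lower <- pmin(pmax(est$lower, 0), 1)
    est$upper <- pmin(pmax(est$upper, 0), 1)
  }
  attr(est, "sigma2") <- sigma2
  attr(est, "replicates") <- p_mat
  est
}
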