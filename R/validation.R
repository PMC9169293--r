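# Out-of-sample evaluation: k-fold cross-validated predictions, accuracy /
# AUC / MSE (Brier) / NLL, ROC and calibration curves, and region-estimate
# comparison reports.

#' K-fold out-of-sample predictions
#'
#' Respondents are shuffled into k mutually exclusive folds (sizes differing
#' by at most one); each respondent's prediction comes from a model whose
#' training data excluded their fold, so the assembled vector is fully
#' out-of-sample.
#'
#' @param X respondent feature table.
#' @param y observed responses.
#' @param predictor a `sae_predictor` (refitted k times).
#' @param k number of folds.
#' @param seed fold-assignment seed.
#' @return list with `predictions` (numeric, one per respondent) and `fold`
#'   (integer assignments).
#' @export
kfold_oos_predictions <- function(X, y, predictor, k = 5L, seed = 1L) {
  n <- length(y)
  if (k < 2L) stop("k must be >= 2")
  if (n < k) stop("fewer respondents than folds")
  set.seed(derive_seed(seed, "cvfolds"))
  fold <- sample(rep(seq_len(k), length.out = n))
  pred <- rep(NA_real_, n)
  for (i in seq_len(k)) {
    te <- fold == i
    fit <- fit_predictor(predictor, X[!te, , drop = FALSE], y[!te])
    pred[te] <- predict(fit, X[te, , drop = FALSE])
  }
  list(predictions = pred, fold = fold)
}

#' Accuracy, AUC, MSE (Brier) and NLL
#'
#' MSE is `(1/n) sum (y_i - f(x_i))^2` — the Brier score for binary
#' outcomes. NLL is the per-observation negative log-likelihood (predictions
#' clamped 1e-12 from the boundary). Accuracy classifies at `p >= threshold`.
#' AUC is the exact pairwise rank statistic: the fraction of
#' (positive, negative) pairs ranked correctly, ties counted 1/2.
#' For continuous outcomes only MSE is reported.
#'
#' @param labels observed responses.
#' @param predictions model mean predictions.
#' @param threshold classification threshold for accuracy.
#' @param outcome `"binary"` or `"continuous"`; default guesses from labels.
#' @return a `metrics_report` (list): `accuracy`, `auc`, `mse`, `nll`, `n`.
#' @export
compute_metrics <- function(labels, predictions, threshold = 0.5,
                            outcome = NULL) {
  stopifnot(length(labels) == length(predictions))
  if (is.null(outcome))
    outcome <- if (is_binary(labels)) "binary" else "continuous"
  n <- length(labels)
  mse <- mean((labels - predictions)^2)
  if (outcome == "continuous") {
    return(structure(list(accuracy = NA_real_, auc = NA_real_, mse = mse,
                          nll = NA_real_, n = n), class = "metrics_report"))
  }
  if (any(predictions < 0 | predictions > 1))
    stop("binary metrics require predictions in [0, 1]")
  acc <- mean((predictions >= threshold) == labels)
  p <- pmin(pmax(predictions, 1e-12), 1 - 1e-12)
  nll <- -mean(labels * log(p) + (1 - labels) * log(1 - p))
  n1 <- sum(labels == 1)
  n0 <- n - n1
  auc <- if (n1 == 0L || n0 == 0L) NA_real_ else {
    r <- rank(predictions)                      # mid-ranks: ties count 1/2
    (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  structure(list(accuracy = acc, auc = auc, mse = mse, nll = nll, n = n),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("n=%d  accuracy=%.4f  AUC=%.4f  MSE=%.4f  NLL=%.4f\n",
              x$n, x$accuracy, x$auc, x$mse, x$nll))
  invisible(x)
}

#' ROC curve points at evenly spaced thresholds
#'
#' Thresholds are evenly spaced over `[0, 1]`; at each, the classification
#' rule is `p >= threshold` and the false/true positive rates are computed.
#'
#' @param labels binary labels with both classes present.
#' @param predictions probabilities in `[0, 1]`.
#' @param n_thresholds number of thresholds (>= 2).
#' @return data.frame with `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(labels, predictions, n_thresholds = 100L) {
  if (n_thresholds < 2L) stop("n_thresholds must be >= 2")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L)
    stop("ROC undefined: labels are all one class")
  thr <- seq(0, 1, length.out = n_thresholds)
  tpr <- vapply(thr, function(t) sum(predictions >= t & labels == 1) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(predictions >= t & labels == 0) / n0, numeric(1))
  data.frame(threshold = thr, fpr = fpr, tpr = tpr)
}

#' Calibration curve by prediction quantile bins
#'
#' Respondents are sorted by predicted probability and cut into
#' `n_bins` equal-count quantile bins; tied predictions are kept in one bin
#' (bins whose boundary would split a tie group are merged). Each bin
#' reports the mean predicted probability and the observed fraction of 1s.
#'
#' @param labels binary labels.
#' @param predictions probabilities.
#' @param n_bins target number of quantile bins.
#' @return data.frame with `bin`, `n`, `mean_predicted`, `observed_fraction`.
#' @export
calibration_bins <- function(labels, predictions, n_bins = 100L) {
  n <- length(labels)
  stopifnot(n == length(predictions), n_bins >= 1L)
  if (n_bins > n) {
    warning("n_bins exceeds sample size; reduced to ", n)
    n_bins <- n
  }
  o <- order(predictions)
  p <- predictions[o]
  y <- labels[o]
  bin <- ceiling(seq_len(n) * n_bins / n)
  # ties stay together: every element of a tie group takes the group's first bin
  first_of_group <- match(p, p)           # index of first occurrence in sorted order
  bin <- bin[first_of_group]
  bin <- match(bin, sort(unique(bin)))    # relabel to consecutive ids
  data.frame(
    bin = sort(unique(bin)),
    n = as.integer(table(bin)),
    mean_predicted = as.numeric(tapply(p, bin, mean)),
    observed_fraction = as.numeric(tapply(y, bin, mean))
  )
}

#' Compare two region-estimate tables
#'
#' Reports the Pearson correlation of the two estimate vectors and the
#' distribution of absolute differences over fixed-width bins
#' (default `[0, 0.025), [0.025, 0.05), ...` up to 0.125, plus an overflow
#' bin) as percentages of regions. Optionally, supplying individual-level
#' out-of-sample labels/predictions and each individual's region code adds
#' an MSE breakdown by region-size quantile.
#'
#' @param est_a,est_b region-estimate tables covering the same regions
#'   (columns `region_code`, `estimate`, `n_population`).
#' @param breaks difference-bin edges (right-open).
#' @param labels,predictions,region optional individual-level data for the
#'   size-stratified MSE.
#' @param n_size_quantiles number of region-size strata.
#' @return list with `pearson`, `diff_table`, and `mse_by_size` when
#'   individual data are given.
#' @export
compare_region_estimates <- function(est_a, est_b,
                                     breaks = seq(0, 0.125, by = 0.025),
                                     labels = NULL, predictions = NULL,
                                     region = NULL, n_size_quantiles = 10L) {
  only_a <- setdiff(est_a$region_code, est_b$region_code)
  only_b <- setdiff(est_b$region_code, est_a$region_code)
  if (length(only_a) || length(only_b))
    stop("region sets differ; only in A: [",
         paste(utils::head(only_a, 5), collapse = ", "), "], only in B: [",
         paste(utils::head(only_b, 5), collapse = ", "), "]")
  b <- est_b[match(est_a$region_code, est_b$region_code), ]
  pearson <- stats::cor(est_a$estimate, b$estimate)

  d <- abs(est_a$estimate - b$estimate)
  edges <- c(breaks, Inf)
  cuts <- cut(d, edges, right = FALSE)
  diff_table <- data.frame(
    bin_lower = edges[-length(edges)],
    bin_upper = edges[-1],
    pct_regions = 100 * as.numeric(table(cuts)) / length(d)
  )

  out <- list(pearson = pearson, diff_table = diff_table)
  if (!is.null(labels) && !is.null(predictions) && !is.null(region)) {
    sizes <- est_a$n_population[match(region, est_a$region_code)]
    if (anyNA(sizes)) stop("individual region code(s) not in estimate table")
    qcut <- ceiling(rank(sizes, ties.method = "first") * n_size_quantiles / length(sizes))
    se <- (labels - predictions)^2
    out$mse_by_size <- data.frame(
      size_quantile = sort(unique(qcut)),
      mean_region_size = as.numeric(tapply(sizes, qcut, mean)),
      mse = as.numeric(tapply(se, qcut, mean)),
      n = as.integer(table(qcut))
    )
  }
  out
}
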