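# Deterministic feature engineering: oblique geographic coordinates, design
# assembly for the predictor contract, and sequential random-forest
# imputation for models that cannot accept missing values.

#' Oblique geographic coordinate configuration
#'
#' @param n_angles number of projection directions K (>= 1); angles are
#'   `theta_k = pi * (k - 1) / K`, all in `[0, pi)`.
#' @param include_raw_xy keep the raw x/y columns alongside the oblique
#'   features.
#' @return an `ogc_config` object.
#' @export
ogc_config <- function(n_angles = 24L, include_raw_xy = FALSE) {
  if (n_angles < 1) stop("n_angles must be >= 1")
  structure(list(n_angles = as.integer(n_angles),
                 include_raw_xy = isTRUE(include_raw_xy)),
            class = "ogc_config")
}

ogc_angles <- function(config) pi * (seq_len(config$n_angles) - 1) / config$n_angles

#' Oblique geographic coordinates
#'
#' Projects each point onto K equally spaced directions in `[0, pi)`, giving
#' axis-aligned tree splits access to oblique spatial boundaries. The polar
#' form `sqrt(x^2 + y^2) * cos(theta_k - atan2(y, x))` is algebraically the
#' linear projection `x * cos(theta_k) + y * sin(theta_k)`; the two-argument
#' arctangent makes the polar form quadrant-safe (for positive x, as in Dutch
#' map coordinates, it coincides with `atan(y/x)`). The origin maps to the
#' all-zero feature vector (the limit of the projection).
#'
#' @param x,y coordinates in meters (equal-length numeric vectors).
#' @param config an [ogc_config()].
#' @param method `"projection"` (default) or `"polar"`; both give identical
#'   results to floating-point accuracy and exist so either form can serve as
#'   a cross-check of the other.
#' @return numeric matrix with `length(x)` rows and K columns `ogc_01`, ...
#' @export
ogc_transform <- function(x, y, config = ogc_config(), method = c("projection", "polar")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  theta <- ogc_angles(config)
  at_origin <- x == 0 & y == 0
  if (any(at_origin))
    message(sum(at_origin), " point(s) at the origin mapped to all-zero OGC features")
  out <- if (method == "projection") {
    outer(x, cos(theta)) + outer(y, sin(theta))
  } else {
    r <- sqrt(x^2 + y^2)
    phi <- atan2(y, x)
    phi[at_origin] <- 0
    r * cos(outer(-phi, theta, `+`))
  }
  colnames(out) <- sprintf("ogc_%02d", seq_len(config$n_angles))
  out
}

frame_feature_columns <- function(frame) {
  reserved <- c("id", "region_nbhd", "region_district", "region_muni",
                "x_coord_m", "y_coord_m", "survey_flag", "response")
  setdiff(names(frame), reserved)
}

#' Assemble a model-ready design table
#'
#' Extracts the feature columns of a population frame and attaches the
#' spatial representation: raw coordinates (`spatial_mode = "xy"`) or K
#' oblique projections (`spatial_mode = "ogc"`, raw coordinates kept only if
#' the OGC config says so). Missing values are preserved — imputation is a
#' separate, explicit step for predictors that need it. With
#' `encoding = "indicator"` each categorical becomes full-rank indicator
#' columns (L - 1 per L-level factor, missing propagated); with
#' `encoding = "level"` factors are passed through for predictors that split
#' on levels natively.
#'
#' @param frame a population frame.
#' @param spatial_mode `"xy"` or `"ogc"`.
#' @param ogc an [ogc_config()] (used when `spatial_mode = "ogc"`).
#' @param encoding `"level"` or `"indicator"`.
#' @return a data.frame of features; attribute `"schema"` records each
#'   column's kind.
#' @export
build_design <- function(frame, spatial_mode = c("xy", "ogc"),
                         ogc = ogc_config(), encoding = c("level", "indicator")) {
  spatial_mode <- match.arg(spatial_mode)
  encoding <- match.arg(encoding)
  cols <- frame_feature_columns(frame)
  X <- frame[, cols, drop = FALSE]

  if (encoding == "indicator") {
    enc <- list()
    for (nm in names(X)) {
      v <- X[[nm]]
      if (is.factor(v) || is.character(v)) {
        v <- as.factor(v)
        lev <- levels(v)
        for (l in lev[-1]) {      # full-rank: L-1 indicators, reference first level
          enc[[paste0(nm, "=", l)]] <- as.numeric(v == l)
        }
      } else {
        enc[[nm]] <- v
      }
    }
    X <- as.data.frame(enc, check.names = FALSE, optional = TRUE)
  }

  if (spatial_mode == "xy") {
    X$x_coord_m <- frame$x_coord_m
    X$y_coord_m <- frame$y_coord_m
  } else {
    if (isTRUE(ogc$include_raw_xy)) {
      X$x_coord_m <- frame$x_coord_m
      X$y_coord_m <- frame$y_coord_m
    }
    X <- cbind(X, as.data.frame(ogc_transform(frame$x_coord_m, frame$y_coord_m, ogc)))
  }
  rownames(X) <- NULL
  attr(X, "schema") <- vapply(X, function(v)
    if (is.factor(v) || is.character(v)) "categorical" else "continuous", character(1))
  X
}

#' Sequential random-forest imputation
#'
#' Features are processed in ascending order of missing fraction (ties broken
#' by column position). For each incomplete feature a random forest is
#' trained on the currently complete columns using the rows where the feature
#' is observed, and its missing entries are filled with forest predictions —
#' classification for categorical features, regression for continuous ones.
#' One sequential sweep; observed entries are never altered.
#'
#' @param frame data.frame of features (factors and numerics), or a full
#'   population frame (non-feature columns are passed through untouched).
#' @param seed integer seed for the forests.
#' @param num_trees trees per forest.
#' @return the frame with no missing feature values.
#' @export
sequential_impute <- function(frame, seed = 1L, num_trees = 100L) {
  cols <- frame_feature_columns(frame)
  X <- frame[, cols, drop = FALSE]
  for (nm in names(X)) if (is.character(X[[nm]])) X[[nm]] <- factor(X[[nm]])

  miss_frac <- vapply(X, function(v) mean(is.na(v)), numeric(1))
  if (all(miss_frac == 0)) return(frame)
  if (any(miss_frac == 1))
    stop("feature(s) 100% missing, nothing to learn from: ",
         paste(names(X)[miss_frac == 1], collapse = ", "))
  if (!any(miss_frac == 0))
    stop("sequential imputation requires at least one fully observed feature")

  order_idx <- order(miss_frac, seq_along(miss_frac))  # ascending, stable
  complete <- names(X)[miss_frac == 0]
  k <- 0L
  for (j in order_idx) {
    nm <- names(X)[j]
    if (miss_frac[j] == 0) next
    k <- k + 1L
    obs <- !is.na(X[[nm]])
    train <- X[obs, complete, drop = FALSE]
    train$.target <- X[[nm]][obs]
    fit <- ranger::ranger(
      dependent.variable.name = ".target", data = train,
      num.trees = num_trees, seed = derive_seed(seed, "impute", k),
      num.threads = 1L, respect.unordered.factors = "order")
    pred <- stats::predict(fit, X[!obs, complete, drop = FALSE],
                           num.threads = 1L)$predictions
    filled <- X[[nm]]
    filled[!obs] <- if (is.factor(filled)) as.character(pred) else pred
    X[[nm]] <- filled
    complete <- c(complete, nm)
  }
  out <- frame
  out[cols] <- X
  attr(out, "impute_order") <- names(X)[order_idx][miss_frac[order_idx] > 0]
  out
}
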