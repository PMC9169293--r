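# Predictor contract: any model exposing fit-on-survey / predict-mean
# behavior plugs into the estimator. Predictions are mean responses —
# probabilities for binary outcomes, real values for ratings.

#' Construct a predictor (model factory)
#'
#' @param name display name.
#' @param fit `function(X, y)` returning any fitted object.
#' @param predict_fun `function(fitted, X)` returning mean predictions.
#' @param missing_ok does the model accept missing feature values?
#' @param encoding preferred categorical encoding for [build_design()]:
#'   `"level"` (native factor splits) or `"indicator"`.
#' @return a `sae_predictor` object.
#' @export
new_predictor <- function(name, fit, predict_fun, missing_ok = TRUE,
                          encoding = c("level", "indicator")) {
  encoding <- match.arg(encoding)
  structure(list(name = name, fit = fit, predict_fun = predict_fun,
                 missing_ok = missing_ok, encoding = encoding),
            class = "sae_predictor")
}

#' Fit a predictor to survey data
#'
#' @param predictor a `sae_predictor`.
#' @param X feature table of respondents.
#' @param y observed responses.
#' @return a `sae_fitted` object usable with `predict()`.
#' @export
fit_predictor <- function(predictor, X, y) {
  stopifnot(inherits(predictor, "sae_predictor"))
  if (length(y) < 1L) stop("cannot fit on an empty survey")
  fitted <- predictor$fit(X, y)
  structure(list(name = predictor$name, fitted = fitted,
                 predict_fun = predictor$predict_fun),
            class = "sae_fitted")
}

#' @export
predict.sae_fitted <- function(object, newdata, ...) {
  object$predict_fun(object$fitted, newdata)
}

#' Null model: predicts the survey mean everywhere
#'
#' Every individual — and therefore every region — receives the overall
#' respondent mean (prevalence or average rating).
#'
#' @return a `sae_predictor`.
#' @export
predictor_null <- function() {
  new_predictor(
    name = "null",
    fit = function(X, y) {
      if (length(y) == 0L) stop("cannot fit null model on an empty survey")
      list(mean = mean(y))
    },
    predict_fun = function(fitted, X) rep(fitted$mean, nrow(X)),
    missing_ok = TRUE
  )
}

#' Fit the null model directly to survey responses
#'
#' @param y observed responses (length >= 1).
#' @return a `sae_fitted` constant predictor.
#' @export
fit_null <- function(y) {
  fit_predictor(predictor_null(), data.frame(row = seq_along(y)), y)
}

#' Reference gradient-boosted-trees predictor
#'
#' Wraps [boost()] in the predictor contract. Handles missing values and
#' factor features natively.
#'
#' @param config a [gbt_config()].
#' @return a `sae_predictor`.
#' @export
predictor_gbt_ref <- function(config = gbt_config()) {
  new_predictor(
    name = "gbt-ref",
    fit = function(X, y) boost(X, y, config),
    predict_fun = function(fitted, X) predict(fitted, X, type = "response"),
    missing_ok = TRUE,
    encoding = "level"
  )
}

design_to_matrix <- function(X) {
  if (is.matrix(X)) return(X)
  bad <- names(X)[vapply(X, function(v) is.factor(v) || is.character(v), logical(1))]
  if (length(bad))
    stop("library booster needs numeric columns; encode categoricals first: ",
         paste(bad, collapse = ", "))
  m <- as.matrix(X)
  storage.mode(m) <- "double"
  m
}

#' Library booster adapter (xgboost)
#'
#' Satisfies the same contract as [predictor_gbt_ref()] through the xgboost
#' library for production-scale runs. Expects an indicator-encoded design
#' (see [build_design()]); missing values are passed through and handled by
#' the booster's learned default directions. With `early_stopping = TRUE`
#' the number of rounds is chosen by `cv_folds`-fold cross-validation with a
#' 10-round patience, capped at `n_rounds`.
#'
#' @param loss `"squared"` or `"logistic"`.
#' @param learning_rate shrinkage (eta).
#' @param n_rounds boosting rounds (cap under early stopping).
#' @param max_depth tree depth.
#' @param early_stopping choose rounds by cross-validation.
#' @param cv_folds folds for early stopping.
#' @param seed integer seed.
#' @return a `sae_predictor`.
#' @export
predictor_gbt_lib <- function(loss = c("logistic", "squared"),
                              learning_rate = 0.3, n_rounds = 50L,
                              max_depth = 6L, early_stopping = FALSE,
                              cv_folds = 5L, seed = 1L) {
  loss <- match.arg(loss)
  objective <- if (loss == "logistic") "binary:logistic" else "reg:squarederror"
  params <- list(objective = objective, eta = learning_rate,
                 max_depth = max_depth, nthread = 1L)
  new_predictor(
    name = "gbt-lib",
    fit = function(X, y) {
      m <- design_to_matrix(X)
      dtrain <- xgboost::xgb.DMatrix(m, label = y, missing = NA)
      rounds <- n_rounds
      if (early_stopping) {
        set.seed(derive_seed(seed, "xgbcv"))
        cv <- xgboost::xgb.cv(params = params, data = dtrain, nrounds = n_rounds,
                              nfold = cv_folds, early_stopping_rounds = 10L,
                              verbose = FALSE)
        rounds <- max(cv$early_stop$best_iteration %||% cv$best_iteration, 1L)
      }
      bst <- xgboost::xgb.train(params = params, data = dtrain, nrounds = rounds)
      list(bst = bst, feature_names = colnames(m))
    },
    predict_fun = function(fitted, X) {
      m <- design_to_matrix(X)
      m <- m[, fitted$feature_names, drop = FALSE]
      as.numeric(predict(fitted$bst, xgboost::xgb.DMatrix(m, missing = NA)))
    },
    missing_ok = TRUE,
    encoding = "indicator"
  )
}

#' Formula-based GLM predictor
#'
#' Plugs an ordinary (generalized) linear model into the predictor contract,
#' e.g. as a comparator model or as a correctly specified classifier in
#' simulation studies where the true outcome surface is known. Missing
#' values are handled before fitting: factor features get an explicit
#' `"(missing)"` level and continuous features are mean-filled with a
#' companion `<name>_missing` indicator available to the formula.
#'
#' @param formula model formula in terms of the design-table columns, with
#'   response `y` (e.g. `y ~ sex + education + I(age >= 65)`).
#' @param family a [stats::family()]; `binomial()` for prevalences,
#'   `gaussian()` for ratings.
#' @return a `sae_predictor`.
#' @export
predictor_glm <- function(formula, family = stats::binomial()) {
  prep <- function(X) {
    for (nm in names(X)) {
      v <- X[[nm]]
      if (is.factor(v) || is.character(v)) {
        v <- as.factor(v)
        if (anyNA(v)) {
          lv <- c(levels(v), "(missing)")
          v <- factor(ifelse(is.na(v), "(missing)", as.character(v)), levels = lv)
        }
        X[[nm]] <- v
      } else if (anyNA(v)) {
        X[[paste0(nm, "_missing")]] <- as.numeric(is.na(v))
        v[is.na(v)] <- mean(v, na.rm = TRUE)
        X[[nm]] <- v
      }
    }
    X
  }
  new_predictor(
    name = "glm",
    fit = function(X, y) {
      d <- prep(X)
      d$y <- y
      stats::glm(formula, family = family, data = d)
    },
    predict_fun = function(fitted, X) {
      as.numeric(stats::predict(fitted, newdata = prep(X), type = "response"))
    },
    missing_ok = TRUE,
    encoding = "level"
  )
}

#' Select boosting rounds by cross-validation (library booster)
#'
#' Runs `cv_folds`-fold cross-validation once with the library booster and
#' returns the best iteration (10-round patience). Used to fix the number of
#' rounds before bootstrap resampling, where re-running the selection on
#' every replicate would be wasteful: the selected capacity is treated as
#' part of the model specification.
#'
#' @inheritParams predictor_gbt_lib
#' @param X indicator-encoded design table of respondents.
#' @param y observed responses.
#' @return best number of rounds (integer >= 1).
#' @export
gbt_lib_select_rounds <- function(X, y, loss = c("logistic", "squared"),
                                  learning_rate = 0.1, n_rounds = 500L,
                                  max_depth = 6L, cv_folds = 5L, seed = 1L) {
  loss <- match.arg(loss)
  objective <- if (loss == "logistic") "binary:logistic" else "reg:squarederror"
  m <- design_to_matrix(X)
  dtrain <- xgboost::xgb.DMatrix(m, label = y, missing = NA)
  set.seed(derive_seed(seed, "xgbcv"))
  cv <- xgboost::xgb.cv(params = list(objective = objective, eta = learning_rate,
                                      max_depth = max_depth, nthread = 1L),
                        data = dtrain, nrounds = n_rounds, nfold = cv_folds,
                        early_stopping_rounds = 10L, verbose = FALSE)
  max(cv$early_stop$best_iteration %||% 1L, 1L)
}

#' Resolve a predictor by name
#'
#' @param model `"null"`, `"gbt-ref"` or `"gbt-lib"`.
#' @param loss loss family name.
#' @param learning_rate,n_rounds,max_depth,early_stopping,cv_folds,seed
#'   hyperparameters forwarded to the chosen predictor.
#' @return a `sae_predictor`.
#' @export
make_predictor <- function(model = c("gbt-lib", "gbt-ref", "null"),
                           loss = c("logistic", "squared"),
                           learning_rate = 0.3, n_rounds = 50L, max_depth = 6L,
                           early_stopping = FALSE, cv_folds = 5L, seed = 1L) {
  model <- match.arg(model)
  loss <- match.arg(loss)
  switch(model,
    "null" = predictor_null(),
    "gbt-ref" = predictor_gbt_ref(gbt_config(
      learning_rate = learning_rate, n_rounds = n_rounds, max_depth = max_depth,
      loss = loss, early_stopping = early_stopping, cv_folds = cv_folds,
      seed = seed)),
    "gbt-lib" = predictor_gbt_lib(
      loss = loss, learning_rate = learning_rate, n_rounds = n_rounds,
      max_depth = max_depth, early_stopping = early_stopping,
      cv_folds = cv_folds, seed = seed))
}
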