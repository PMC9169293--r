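# End-to-end orchestration: simulation or file input -> feature engineering
# -> model fit -> region estimates with intervals -> validation reports,
# with one master seed split into named substreams and a machine-readable
# run manifest.

surface_from_config <- function(sim) {
  if (!is.null(sim$surface) && identical(sim$surface, "default")) return(default_surface())
  if (is.null(sim$surface)) return(default_surface())
  stop("unknown surface spec: ", sim$surface)
}

#' Run the full estimation pipeline
#'
#' Configuration keys (YAML file via [read_run_config()] or an R list):
#' \describe{
#'   \item{input}{path to a population table; or instead `simulate:` with
#'     `n_individuals`, `n_municipalities`, `n_districts_per`,
#'     `n_neighborhoods_per`, `surface` ("default"), `sampling_fraction`.}
#'   \item{model}{`name` ("null", "gbt-ref", "gbt-lib"), `loss` ("logistic"
#'     or "squared"), `learning_rate`, `n_rounds`, `max_depth`,
#'     `early_stopping`, `cv_folds`.}
#'   \item{spatial_mode}{"xy" or "ogc"; `ogc_k` angles (default 24).}
#'   \item{impute}{"none" or "sequential".}
#'   \item{levels}{character vector of levels to estimate.}
#'   \item{bootstrap}{`n_replicates` (0 disables intervals), `nominal_level`.}
#'   \item{validate}{logical: 5-fold out-of-sample metrics report.}
#'   \item{output_dir}{directory for artifacts.}
#' }
#' Every stochastic stage consumes a seed derived from `seed` by
#' [derive_seed()]; identical config + seed gives byte-identical outputs.
#'
#' @param config named list (or path handled by caller).
#' @param seed master seed; overrides `config$seed` when given.
#' @return invisible list with `estimates` (per level), `metrics`,
#'   `manifest`, and the frame used.
#' @export
run_pipeline <- function(config, seed = NULL) {
  seed <- as.integer(seed %||% config$seed %||% 1L)
  out_dir <- config$output_dir %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }

  # --- input ---------------------------------------------------------------
  outcome <- config$outcome %||% "binary"
  if (!is.null(config$input)) {
    say("stage=input reading %s", config$input)
    frame <- read_population_table(config$input)
  } else {
    sim <- config$simulate %||% list()
    pc <- population_config(
      n_individuals = sim$n_individuals %||% 20000L,
      n_municipalities = sim$n_municipalities %||% 4L,
      n_districts_per = sim$n_districts_per %||% 5L,
      n_neighborhoods_per = sim$n_neighborhoods_per %||% 5L,
      seed = derive_seed(seed, "simulation"))
    say("stage=simulate n=%d seed_stream=simulation", pc$n_individuals)
    pop <- generate_population(pc, surface_from_config(sim))
    frame <- sample_survey(pop$frame, survey_design(
      sampling_fraction = sim$sampling_fraction %||% 0.1,
      seed = derive_seed(seed, "survey")))
  }

  # --- features ------------------------------------------------------------
  if (identical(config$impute %||% "none", "sequential")) {
    say("stage=impute method=sequential seed_stream=imputation")
    frame <- sequential_impute(frame, seed = derive_seed(seed, "imputation"))
  }
  model_cfg <- config$model %||% list()
  model_name <- model_cfg$name %||% "gbt-lib"
  predictor <- make_predictor(
    model = model_name,
    loss = model_cfg$loss %||% (if (outcome == "binary") "logistic" else "squared"),
    learning_rate = model_cfg$learning_rate %||% 0.3,
    n_rounds = model_cfg$n_rounds %||% 50L,
    max_depth = model_cfg$max_depth %||% 6L,
    early_stopping = isTRUE(model_cfg$early_stopping),
    cv_folds = model_cfg$cv_folds %||% 5L,
    seed = derive_seed(seed, "model"))
  spatial_mode <- config$spatial_mode %||% "xy"
  ogc <- ogc_config(n_angles = config$ogc_k %||% 24L)
  say("stage=design spatial_mode=%s encoding=%s", spatial_mode, predictor$encoding)
  X <- build_design(frame, spatial_mode, ogc, encoding = predictor$encoding)

  # --- fit + estimates -----------------------------------------------------
  surveyed <- frame$survey_flag == 1L
  say("stage=fit model=%s respondents=%d", model_name, sum(surveyed))
  fitted <- fit_predictor(predictor, X[surveyed, , drop = FALSE],
                          frame$response[surveyed])
  boot_cfg <- config$bootstrap %||% list()
  B <- boot_cfg$n_replicates %||% 0L
  nominal <- boot_cfg$nominal_level %||% 0.95
  levels_req <- config$levels %||% "neighborhood"
  estimates <- list()
  for (lv in levels_req) {
    if (B >= 1L) {
      say("stage=estimate level=%s bootstrap=%d seed_stream=bootstrap", lv, B)
      est <- bootstrap_prediction_intervals(
        frame, X, predictor, level = lv, outcome = outcome,
        n_replicates = B, nominal_level = nominal,
        seed = derive_seed(seed, "bootstrap"), point_fitted = fitted)
      attr(est, "replicates") <- NULL
    } else {
      say("stage=estimate level=%s (point estimates only)", lv)
      ystar <- combine_predicted_responses(frame, fitted, X)
      est <- aggregate_regions(ystar, frame, lv, nominal)
    }
    estimates[[lv]] <- est
    write_estimates_table(est, file.path(out_dir, paste0("estimates_", lv, ".csv")))
  }

  # --- validation ----------------------------------------------------------
  metrics <- NULL
  if (isTRUE(config$validate)) {
    say("stage=validate folds=5 seed_stream=cv")
    oos <- kfold_oos_predictions(X[surveyed, , drop = FALSE],
                                 frame$response[surveyed], predictor,
                                 k = 5L, seed = derive_seed(seed, "cv"))
    metrics <- compute_metrics(frame$response[surveyed], oos$predictions,
                               outcome = outcome)
    jsonlite::write_json(unclass(metrics),
                         file.path(out_dir, paste0("metrics_", model_name, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }

  manifest <- list(
    package = "saeboost",
    version = as.character(utils::packageVersion("saeboost")),
    seed = seed,
    seed_streams = list(simulation = derive_seed(seed, "simulation"),
                        survey = derive_seed(seed, "survey"),
                        imputation = derive_seed(seed, "imputation"),
                        model = derive_seed(seed, "model"),
                        bootstrap = derive_seed(seed, "bootstrap"),
                        cv = derive_seed(seed, "cv")),
    config_hash = config_hash(config),
    model = model_name,
    levels = levels_req,
    n_individuals = nrow(frame),
    n_respondents = sum(surveyed)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(list(estimates = estimates, metrics = metrics,
                 manifest = manifest, frame = frame))
}
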