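# File round-trips: delimited population tables (UTF-8, comma separator,
# dot decimal, empty field = missing), estimates tables, and YAML run
# configuration.

POP_MANDATORY <- c("id", "region_nbhd", "region_district", "region_muni",
                   "x_coord_m", "y_coord_m", "survey_flag", "response")

#' Write a population frame as delimited text
#'
#' Columns: id, region codes, coordinates, survey flag, response, then
#' feature columns. Missing values become empty fields.
#'
#' @param frame population frame.
#' @param path output path.
#' @export
write_population_table <- function(frame, path) {
  utils::write.csv(frame, path, row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a delimited population table
#'
#' Validates the mandatory columns, the survey flag domain and
#' flag/response consistency; empty fields become missing values and
#' character feature columns become factors.
#'
#' @param path input path.
#' @return a population frame.
#' @export
read_population_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  frame <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8")
  missing_cols <- setdiff(POP_MANDATORY, names(frame))
  if (length(missing_cols))
    stop("missing column ", paste(missing_cols, collapse = ", "))
  if (!all(frame$survey_flag %in% c(0L, 1L)))
    stop("survey_flag values outside {0,1}")
  bad <- frame$survey_flag == 1L & is.na(frame$response)
  if (any(bad))
    stop("respondent row(s) with empty response: id ",
         paste(utils::head(frame$id[bad], 5), collapse = ", "))
  for (nm in frame_feature_columns(frame)) {
    if (is.character(frame[[nm]])) frame[[nm]] <- factor(frame[[nm]])
  }
  frame
}

#' Write a region-estimates table
#'
#' Delimited text with columns level, region_code, n_population,
#' n_respondents, estimate, lower, upper, nominal_level; sorted by level
#' then region code, numbers at 6 significant digits, missing = empty.
#'
#' @param estimates one or more [aggregate_regions()] tables (row-bound).
#' @param path output path.
#' @export
write_estimates_table <- function(estimates, path) {
  est <- estimates[order(estimates$level, estimates$region_code), , drop = FALSE]
  for (nm in c("estimate", "lower", "upper", "nominal_level"))
    est[[nm]] <- signif(est[[nm]], 6)
  utils::write.csv(est, path, row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a region-estimates table
#' @param path file written by [write_estimates_table()].
#' @return data.frame.
#' @export
read_estimates_table <- function(path) {
  utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE,
                  fileEncoding = "UTF-8")
}

#' Read a run configuration file (YAML key-value format)
#'
#' See [run_pipeline()] for the recognized keys.
#'
#' @param path YAML file.
#' @return named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  yaml::read_yaml(path)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(config), tmp)
  unname(tools::md5sum(tmp))
}
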