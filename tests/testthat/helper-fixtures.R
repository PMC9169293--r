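# Shared fixtures, all built in code.

small_config <- function(n = 2000L, seed = 42L, ...) {
  population_config(n_individuals = n, n_municipalities = 2L,
                    n_districts_per = 2L, n_neighborhoods_per = 5L,
                    seed = seed, ...)
}

# tiny deterministic frame for estimator/IO tests: 2 municipalities,
# 2 districts each, regions of known sizes
toy_frame <- function() {
  nb <- c(rep("NB01", 4), rep("NB02", 2), rep("NB03", 3), rep("NB04", 1))
  di <- c(rep("DI1", 6), rep("DI2", 4))
  mu <- c(rep("MU1", 6), rep("MU2", 4))
  n <- length(nb)
  data.frame(
    id = seq_len(n),
    region_nbhd = nb, region_district = di, region_muni = mu,
    x_coord_m = seq(1000, 1000 * n, by = 1000),
    y_coord_m = rep(2000, n),
    survey_flag = c(1L, 1L, 0L, 0L, 1L, 0L, 1L, 1L, 0L, 1L),
    response = c(1, 0, NA, NA, 1, NA, 0, 1, NA, 1),
    age = c(25, 40, 60, 35, 50, 45, 70, 30, 55, 65),
    group = factor(c("a", "b", "a", "b", "a", "b", "a", "b", "a", "b")),
    stringsAsFactors = FALSE
  )
}

constant_predictor <- function(value) {
  new_predictor("constant",
                fit = function(X, y) value,
                predict_fun = function(fitted, X) rep(fitted, nrow(X)))
}
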