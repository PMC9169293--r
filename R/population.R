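# Synthetic population generator: region hierarchies, registry-style feature
# tables, known outcome surfaces and survey draws. The generator exists so the
# estimator and validation machinery can be exercised against a known truth;
# real registry microdata are access-restricted.

#' Feature schema entry
#'
#' @param name column name.
#' @param kind `"categorical"` or `"continuous"`.
#' @param levels character vector of levels (categorical only).
#' @param probabilities level probabilities, must sum to 1 (categorical only).
#' @param rng for continuous features, a `function(n)` drawing n values.
#' @param missing_rate fraction of entries set missing, in `[0, 1]`.
#' @return a `feature_spec` list.
#' @export
feature_spec <- function(name, kind = c("categorical", "continuous"),
                         levels = NULL, probabilities = NULL,
                         rng = NULL, missing_rate = 0) {
  kind <- match.arg(kind)
  if (missing_rate < 0 || missing_rate > 1)
    stop("missing_rate must be in [0, 1] for feature '", name, "'")
  if (kind == "categorical") {
    stopifnot(length(levels) >= 2L, length(probabilities) == length(levels))
    if (abs(sum(probabilities) - 1) > 1e-8)
      stop("probabilities for feature '", name, "' must sum to 1")
  } else {
    stopifnot(is.function(rng))
  }
  structure(list(name = name, kind = kind, levels = levels,
                 probabilities = probabilities, rng = rng,
                 missing_rate = missing_rate),
            class = "feature_spec")
}

#' Default registry-style feature schema
#'
#' Mirrors the feature set of Dutch administrative registry data at reduced
#' cardinality: individual-level demographics (age, sex, ethnicity, marital
#' status, education), household variables (type, size, income source, home
#' ownership, income and asset percentiles) and neighborhood address density.
#' Education carries the characteristic 37.8% missingness of registry
#' education records; income-related household variables about 2.4%.
#'
#' @return list of [feature_spec()] objects.
#' @export
default_feature_schema <- function() {
  list(
    feature_spec("age", "continuous",
                 rng = function(n) pmin(pmax(round(stats::rgamma(n, shape = 9, scale = 5.5) + 18), 18), 105)),
    feature_spec("sex", "categorical", c("male", "female"), c(0.49, 0.51)),
    feature_spec("ethnicity", "categorical",
                 c("native", "morocco", "turkey", "suriname", "antilles",
                   "other_nonwestern", "other_western"),
                 c(0.76, 0.03, 0.03, 0.03, 0.01, 0.05, 0.09)),
    feature_spec("marital_status", "categorical",
                 c("single", "married", "divorced", "widowed"),
                 c(0.36, 0.46, 0.11, 0.07), missing_rate = 0.006),
    feature_spec("education", "categorical",
                 c("basis", "vmbo_bk", "vmbo_gt", "mbo23", "mbo4",
                   "havo_vwo", "hbo_wo_bach", "hbo_wo_master"),
                 c(0.08, 0.10, 0.12, 0.14, 0.18, 0.08, 0.19, 0.11),
                 missing_rate = 0.378),
    feature_spec("household_type", "categorical",
                 c("single_person", "couple_no_children", "couple_children",
                   "single_parent", "other"),
                 c(0.30, 0.29, 0.29, 0.07, 0.05)),
    feature_spec("household_size", "continuous",
                 rng = function(n) pmin(1 + stats::rpois(n, 1.2), 10)),
    feature_spec("income_source", "categorical",
                 c("wage", "self_employed", "unemployment_benefit",
                   "social_assistance", "disability_benefit", "pension", "other"),
                 c(0.52, 0.09, 0.02, 0.04, 0.05, 0.24, 0.04),
                 missing_rate = 0.024),
    feature_spec("home_ownership", "categorical",
                 c("owner", "rental_no_allowance", "rental_allowance"),
                 c(0.60, 0.25, 0.15), missing_rate = 0.020),
    feature_spec("income_pct", "continuous",
                 rng = function(n) stats::runif(n, 1, 100), missing_rate = 0.024),
    feature_spec("assets_pct", "continuous",
                 rng = function(n) stats::runif(n, 1, 100), missing_rate = 0.024),
    feature_spec("address_density", "continuous",
                 rng = function(n) stats::runif(n, 1, 100))
  )
}

#' Population configuration
#'
#' @param n_individuals population size N.
#' @param n_municipalities,n_districts_per,n_neighborhoods_per nested region
#'   counts: municipalities, districts per municipality, neighborhoods per
#'   district. Defaults give 100 neighborhoods.
#' @param feature_schema list of [feature_spec()] objects.
#' @param coordinate_extent rectangle `c(xmin, xmax, ymin, ymax)` in meters.
#' @param size_dispersion gamma shape for random neighborhood size weights;
#'   smaller values give more unequal neighborhood sizes.
#' @param seed integer seed controlling all generation.
#' @return a `population_config` object.
#' @export
population_config <- function(n_individuals = 20000L,
                              n_municipalities = 4L,
                              n_districts_per = 5L,
                              n_neighborhoods_per = 5L,
                              feature_schema = default_feature_schema(),
                              coordinate_extent = c(10000, 60000, 10000, 60000),
                              size_dispersion = 2,
                              seed = 1L) {
  counts <- c(n_individuals, n_municipalities, n_districts_per, n_neighborhoods_per)
  if (any(counts < 1)) stop("configuration error: all counts must be >= 1")
  if (length(feature_schema) == 0L) stop("feature_schema must be non-empty")
  stopifnot(length(coordinate_extent) == 4L,
            coordinate_extent[2] > coordinate_extent[1],
            coordinate_extent[4] > coordinate_extent[3])
  structure(list(n_individuals = as.integer(n_individuals),
                 n_municipalities = as.integer(n_municipalities),
                 n_districts_per = as.integer(n_districts_per),
                 n_neighborhoods_per = as.integer(n_neighborhoods_per),
                 feature_schema = feature_schema,
                 coordinate_extent = coordinate_extent,
                 size_dispersion = size_dispersion,
                 seed = as.integer(seed)),
            class = "population_config")
}

#' Generate a nested region hierarchy and individual assignment
#'
#' Neighborhoods tile the coordinate extent on a grid (row-major, so
#' consecutive codes are spatially adjacent); each individual is assigned to
#' one neighborhood with random size weights, so neighborhood populations
#' vary realistically. Neighborhoods nest in districts, districts in
#' municipalities.
#'
#' @param config a [population_config()].
#' @return a `region_hierarchy`: `regions` (one row per neighborhood with its
#'   parent codes and tile bounds) and `assignment` (neighborhood row index
#'   per individual).
#' @export
generate_hierarchy <- function(config) {
  stopifnot(inherits(config, "population_config"))
  set.seed(derive_seed(config$seed, "hierarchy"))
  n_mu <- config$n_municipalities
  n_di <- config$n_districts_per
  n_nb <- config$n_neighborhoods_per
  m <- n_mu * n_di * n_nb

  muni <- rep(seq_len(n_mu), each = n_di * n_nb)
  dist <- rep(seq_len(n_mu * n_di), each = n_nb)
  regions <- data.frame(
    region_nbhd = sprintf("NB%04d", seq_len(m)),
    region_district = sprintf("DI%03d", dist),
    region_muni = sprintf("MU%02d", muni),
    stringsAsFactors = FALSE
  )

  # jittered grid tiling of the extent
  ext <- config$coordinate_extent
  nx <- ceiling(sqrt(m))
  ny <- ceiling(m / nx)
  col <- (seq_len(m) - 1L) %% nx
  row <- (seq_len(m) - 1L) %/% nx
  w <- (ext[2] - ext[1]) / nx
  h <- (ext[4] - ext[3]) / ny
  regions$x0 <- ext[1] + col * w
  regions$x1 <- regions$x0 + w
  regions$y0 <- ext[3] + row * h
  regions$y1 <- regions$y0 + h

  weights <- stats::rgamma(m, shape = config$size_dispersion, rate = 1)
  weights <- weights / sum(weights)
  assignment <- sample.int(m, config$n_individuals, replace = TRUE, prob = weights)
  structure(list(regions = regions, assignment = assignment,
                 n_individuals = config$n_individuals),
            class = "region_hierarchy")
}

#' Known outcome surface for simulation
#'
#' Defines the true individual-level mean response as
#' `link^-1(intercept + linear terms + level effects + nonlinear terms +
#' interactions + spatial field)`. With the logistic link the outcome is a
#' Bernoulli indicator; with the identity link a Gaussian rating with
#' standard deviation `noise_sd`.
#'
#' @param link `"logistic"` or `"identity"`.
#' @param intercept scalar intercept on the link scale.
#' @param linear named numeric: coefficient per continuous feature (applied
#'   to the feature standardized to roughly unit scale by `scale_ref`).
#' @param scale_ref named list of `c(center, scale)` used to standardize
#'   continuous features before applying `linear`/`nonlinear`.
#' @param levels named list: per categorical feature, a named numeric of
#'   additive effects per level.
#' @param nonlinear named list: per continuous feature, a `function(z)` of the
#'   standardized value returning an additive term.
#' @param interactions list of `list(a =, b =, coef =, level_a =, level_b =)`:
#'   product terms; categorical factors enter as level indicators, continuous
#'   ones as standardized values.
#' @param spatial `function(x, y)` in meters returning an additive smooth term.
#' @param noise_sd residual standard deviation (identity link only, > 0).
#' @return a `true_surface` object.
#' @export
true_surface <- function(link = c("logistic", "identity"),
                         intercept = 0,
                         linear = numeric(0),
                         scale_ref = list(),
                         levels = list(),
                         nonlinear = list(),
                         interactions = list(),
                         spatial = NULL,
                         noise_sd = NULL) {
  link <- match.arg(link)
  if (link == "identity") {
    if (is.null(noise_sd) || noise_sd <= 0)
      stop("identity link requires noise_sd > 0")
  }
  structure(list(link = link, intercept = intercept, linear = linear,
                 scale_ref = scale_ref, levels = levels, nonlinear = nonlinear,
                 interactions = interactions, spatial = spatial,
                 noise_sd = noise_sd),
            class = "true_surface")
}

#' Default logistic outcome surface
#'
#' Emulates a health-indicator prevalence surface (~30% nationally) with
#' nonlinear age dependence, demographic main effects, an education gradient,
#' an income effect, an age-by-sex interaction and a smooth sinusoidal
#' spatial field — the nonlinearity/interaction/spatial structure unit-level
#' small area models are meant to capture.
#'
#' @param spatial_amplitude amplitude of the spatial field on the logit scale.
#' @param wavelength spatial wavelength in meters.
#' @return a `true_surface` object.
#' @export
default_surface <- function(spatial_amplitude = 0.4, wavelength = 25000) {
  true_surface(
    link = "logistic",
    intercept = -1.1,
    linear = c(income_pct = -0.35),
    scale_ref = list(age = c(50, 20), income_pct = c(50, 30)),
    levels = list(
      sex = c(male = 0.25, female = -0.25),
      education = c(basis = 0.35, vmbo_bk = 0.25, vmbo_gt = 0.15, mbo23 = 0.10,
                    mbo4 = 0.00, havo_vwo = -0.10, hbo_wo_bach = -0.25,
                    hbo_wo_master = -0.40),
      marital_status = c(single = 0.15, married = -0.15, divorced = 0.10,
                         widowed = 0.05)
    ),
    nonlinear = list(age = function(z) 0.5 * z - 0.35 * z^2),
    interactions = list(
      list(a = "sex", level_a = "male", b = "age", coef = 0.30)
    ),
    spatial = function(x, y) {
      spatial_amplitude * sin(2 * pi * x / wavelength) *
        cos(2 * pi * y / wavelength)
    }
  )
}

#' Piecewise-constant logistic outcome surface
#'
#' A surface that is exactly representable by shallow decision trees: strong
#' discrete effects (sex, a three-group education gradient, an age-65 step)
#' plus a checkerboard spatial field with 25 km blocks. Used for interval
#' calibration studies, where the fitted classifier must be correctly
#' specified — tree ensembles estimate the cells of this surface without
#' approximation bias, so bootstrap intervals reflect estimation variance
#' alone. For a realistic smooth surface use [default_surface()].
#'
#' @param spatial_amplitude checkerboard amplitude on the logit scale.
#' @param block_m checkerboard block side in meters.
#' @return a `true_surface` object.
#' @export
piecewise_surface <- function(spatial_amplitude = 0.4, block_m = 25000) {
  true_surface(
    link = "logistic", intercept = -1.0,
    scale_ref = list(age = c(50, 20)),
    levels = list(
      sex = c(male = 0.3, female = -0.3),
      education = c(basis = 0.4, vmbo_bk = 0.4, vmbo_gt = 0.4, mbo23 = 0.0,
                    mbo4 = 0.0, havo_vwo = 0.0, hbo_wo_bach = -0.4,
                    hbo_wo_master = -0.4)),
    nonlinear = list(age = function(z) 0.5 * (z >= 0.75)),
    spatial = function(x, y) {
      spatial_amplitude *
        (((floor(x / block_m) + floor(y / block_m)) %% 2) * 2 - 1)
    })
}

std_value <- function(surface, feature, v) {
  ref <- surface$scale_ref[[feature]]
  if (is.null(ref)) v else (v - ref[1]) / ref[2]
}

# linear predictor of a surface on a complete feature table
surface_eta <- function(surface, feats, x, y) {
  need <- c(names(surface$linear), names(surface$levels), names(surface$nonlinear),
            unlist(lapply(surface$interactions, function(tr) c(tr$a, tr$b))))
  unknown <- setdiff(unique(need), names(feats))
  if (length(unknown))
    stop("surface references unknown feature(s): ", paste(unknown, collapse = ", "))
  eta <- rep(surface$intercept, nrow(feats))
  for (nm in names(surface$linear))
    eta <- eta + surface$linear[[nm]] * std_value(surface, nm, feats[[nm]])
  for (nm in names(surface$levels)) {
    eff <- surface$levels[[nm]]
    eta <- eta + unname(eff[as.character(feats[[nm]])])
  }
  for (nm in names(surface$nonlinear))
    eta <- eta + surface$nonlinear[[nm]](std_value(surface, nm, feats[[nm]]))
  for (tr in surface$interactions) {
    va <- if (!is.null(tr$level_a)) as.numeric(feats[[tr$a]] == tr$level_a)
          else std_value(surface, tr$a, feats[[tr$a]])
    vb <- if (!is.null(tr$level_b)) as.numeric(feats[[tr$b]] == tr$level_b)
          else std_value(surface, tr$b, feats[[tr$b]])
    eta <- eta + tr$coef * va * vb
  }
  if (!is.null(surface$spatial)) eta <- eta + surface$spatial(x, y)
  eta
}

#' Generate a synthetic population with known true means
#'
#' Features are drawn per the schema, coordinates uniformly within each
#' individual's neighborhood tile (so location correlates with region), true
#' means are computed from the surface on the complete features, outcomes are
#' drawn (`Bernoulli` or `Normal`), and missing entries are then introduced at
#' the configured per-feature rates (missing completely at random). The
#' returned frame is a census: all individuals carry `survey_flag = 1` and an
#' observed response; use [sample_survey()] to reduce it to a survey.
#'
#' @param config a [population_config()].
#' @param surface a [true_surface()].
#' @param hierarchy optionally a pre-generated [generate_hierarchy()] result.
#' @return list with `frame` (the population table), `true_means` (numeric
#'   vector of individual true means) and `hierarchy`.
#' @export
generate_population <- function(config, surface = default_surface(),
                                hierarchy = NULL) {
  stopifnot(inherits(config, "population_config"), inherits(surface, "true_surface"))
  if (is.null(hierarchy)) hierarchy <- generate_hierarchy(config)
  n <- config$n_individuals
  set.seed(derive_seed(config$seed, "population"))

  reg <- hierarchy$regions[hierarchy$assignment, ]
  x <- stats::runif(n, reg$x0, reg$x1)
  y <- stats::runif(n, reg$y0, reg$y1)

  feats <- list()
  for (fs in config$feature_schema) {
    feats[[fs$name]] <- if (fs$kind == "categorical") {
      factor(sample(fs$levels, n, replace = TRUE, prob = fs$probabilities),
             levels = fs$levels)
    } else fs$rng(n)
  }
  feats <- as.data.frame(feats, stringsAsFactors = FALSE)

  mu <- surface_eta(surface, feats, x, y)
  if (surface$link == "logistic") {
    mu <- stats::plogis(mu)
    response <- stats::rbinom(n, 1L, mu)
  } else {
    response <- stats::rnorm(n, mu, surface$noise_sd)
  }

  for (fs in config$feature_schema) {
    if (fs$missing_rate > 0) {
      miss <- stats::runif(n) < fs$missing_rate
      feats[[fs$name]][miss] <- NA
    }
  }

  frame <- data.frame(
    id = seq_len(n),
    region_nbhd = reg$region_nbhd,
    region_district = reg$region_district,
    region_muni = reg$region_muni,
    x_coord_m = x, y_coord_m = y,
    survey_flag = 1L,
    response = response,
    stringsAsFactors = FALSE
  )
  frame <- cbind(frame, feats)
  rownames(frame) <- NULL
  list(frame = frame, true_means = mu, hierarchy = hierarchy)
}

#' Survey sampling design
#'
#' @param sampling_fraction overall inclusion probability, in `(0, 1]`.
#' @param bias_feature optional name of a continuous feature; inclusion
#'   probability then increases monotonically with it.
#' @param bias_strength log-scale slope of inclusion probability per standard
#'   deviation of the bias feature (0 = none).
#' @param municipality_fractions optional named vector of per-municipality
#'   sampling fractions approximating a stratified design.
#' @param seed integer seed.
#' @return a `survey_design` object.
#' @export
survey_design <- function(sampling_fraction = 0.1, bias_feature = NULL,
                          bias_strength = 0, municipality_fractions = NULL,
                          seed = 1L) {
  if (sampling_fraction <= 0 || sampling_fraction > 1)
    stop("sampling_fraction must be in (0, 1]")
  structure(list(sampling_fraction = sampling_fraction,
                 bias_feature = bias_feature, bias_strength = bias_strength,
                 municipality_fractions = municipality_fractions,
                 seed = as.integer(seed)),
            class = "survey_design")
}

#' Draw a survey from a population frame
#'
#' Individuals are included independently (Poisson sampling) with probability
#' equal to the sampling fraction, optionally tilted monotonically by a named
#' feature. Responses of unsampled individuals are set missing.
#'
#' @param pop population frame from [generate_population()] (`$frame`).
#' @param design a [survey_design()].
#' @return the frame with `survey_flag` set and non-respondent responses `NA`.
#' @export
sample_survey <- function(pop, design) {
  stopifnot(inherits(design, "survey_design"))
  set.seed(derive_seed(design$seed, "survey"))
  n <- nrow(pop)
  p <- rep(design$sampling_fraction, n)
  if (!is.null(design$municipality_fractions)) {
    f <- design$municipality_fractions[pop$region_muni]
    p <- ifelse(is.na(f), p, f)
  }
  if (!is.null(design$bias_feature) && design$bias_strength != 0) {
    v <- pop[[design$bias_feature]]
    if (is.null(v)) stop("bias_feature '", design$bias_feature, "' not in frame")
    z <- (v - mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE)
    z[is.na(z)] <- 0
    w <- exp(design$bias_strength * z)
    p <- p * w / mean(w)
    p <- pmin(p, 1)
  }
  flag <- as.integer(stats::runif(n) < p)
  pop$survey_flag <- flag
  pop$response[flag == 0L] <- NA
  pop
}

region_column <- function(level) {
  switch(level,
         neighborhood = "region_nbhd",
         district = "region_district",
         municipality = "region_muni",
         national = NULL,
         stop("unknown level '", level, "'"))
}

#' True region means from individual true means
#'
#' @param true_means numeric vector of individual true means.
#' @param frame population frame carrying region codes (row order must match).
#' @param level `"neighborhood"`, `"district"`, `"municipality"` or
#'   `"national"`.
#' @return data.frame with `region_code` and `true_mean`.
#' @export
true_region_means <- function(true_means, frame, level = "neighborhood") {
  if (length(true_means) != nrow(frame))
    stop("true_means must have one entry per individual")
  if (anyNA(true_means)) stop("every individual must have a true mean")
  col <- region_column(level)
  g <- if (is.null(col)) rep("ALL", nrow(frame)) else frame[[col]]
  agg <- tapply(true_means, g, mean)
  data.frame(region_code = names(agg), true_mean = as.numeric(agg),
             stringsAsFactors = FALSE, row.names = NULL)
}
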