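#' Population-level (hyper)parameters of the hierarchical trend model
#'
#' Container for the parameters governing lake-level intercepts, slopes and
#' residual SDs: lake intercept/slope pairs are bivariate normal with means
#' `(mu_beta0, mu_beta1)`, SDs `(sd_beta0, sd_beta1)` and correlation `rho`;
#' natural-log lake residual SDs are normal with mean `mu_logsigma` and SD
#' `sd_logsigma`. Defaults describe a plausible upper-midwest lake
#' population: average summer clarity 2.4 m, average trend +0.92 %/yr, and
#' typical inter-annual variability around 20 % (CV).
#'
#' @param mu_beta0,mu_beta1 Population-average log-scale intercept and slope
#'   (per year).
#' @param sd_beta0,sd_beta1 Among-lake SDs of intercepts and slopes.
#' @param rho Correlation between lake intercept and slope deviations.
#' @param mu_logsigma,sd_logsigma Mean and SD of log-e lake residual SDs.
#' @return An object of class `hyper_params`.
#' @export
hyper_params <- function(mu_beta0 = log(2.4), mu_beta1 = 0.0092,
                         sd_beta0 = 0.5, sd_beta1 = 0.01, rho = -0.2,
                         mu_logsigma = log(0.2), sd_logsigma = 0.5) {
  if (sd_beta0 < 0 || sd_beta1 < 0 || sd_logsigma < 0)
    stop("SDs must be nonnegative")
  if (rho < -1 || rho > 1) stop("rho must lie in [-1, 1]")
  structure(list(mu_beta0 = mu_beta0, mu_beta1 = mu_beta1,
                 sd_beta0 = sd_beta0, sd_beta1 = sd_beta1, rho = rho,
                 mu_logsigma = mu_logsigma, sd_logsigma = sd_logsigma),
            class = "hyper_params")
}

#' Second-stage covariate-effect parameters
#'
#' Linear effects of one standardized lake-level covariate on the lake
#' intercept (`g00 + g01 z`), slope (`g10 + g11 z`) and log residual SD
#' (`h0 + h1 z`). Residual (around-the-line) variation keeps the bivariate
#' intercept/slope correlation structure, and the log-sigma equation has its
#' own residual SD.
#'
#' @param g00,g01 Intercept-equation intercept and covariate coefficient.
#' @param g10,g11 Slope-equation pair.
#' @param h0,h1 Log-residual-SD-equation pair.
#' @param sd_beta0,sd_beta1,rho Residual SDs and correlation of the
#'   second-stage intercept/slope deviations.
#' @param sd_logsigma Residual SD of the log-sigma equation.
#' @return An object of class `covariate_effects`.
#' @export
covariate_effects <- function(g00 = log(2.4), g01 = 0, g10 = 0.0092, g11 = 0,
                              h0 = log(0.2), h1 = 0,
                              sd_beta0 = 0.5, sd_beta1 = 0.01, rho = -0.2,
                              sd_logsigma = 0.5) {
  if (sd_beta0 < 0 || sd_beta1 < 0 || sd_logsigma < 0)
    stop("SDs must be nonnegative")
  if (rho < -1 || rho > 1) stop("rho must lie in [-1, 1]")
  structure(list(g00 = g00, g01 = g01, g10 = g10, g11 = g11,
                 h0 = h0, h1 = h1, sd_beta0 = sd_beta0, sd_beta1 = sd_beta1,
                 rho = rho, sd_logsigma = sd_logsigma),
            class = "covariate_effects")
}

#' Design of a synthetic monitoring cohort
#'
#' Describes the sampling frame of a simulated citizen-monitoring database:
#' number of lakes, the span of calendar years, record lengths, the number of
#' summer readings per lake-year, and contamination rates used to exercise
#' QA/QC (readings logged in feet, >30 m transcription outliers, readings
#' dated outside June-August).
#'
#' @param n_lakes Number of lakes.
#' @param year_range Inclusive calendar span, default `c(1938, 2012)`.
#' @param record_length_range Record lengths drawn uniformly from this
#'   integer range (default `c(1, 34)`), each placed uniformly inside
#'   `year_range`.
#' @param obs_per_summer Integer range for the number of readings per
#'   lake-summer, drawn uniformly (default `c(3, 12)`, about 7 on average).
#' @param within_summer_sd SD, on the log scale, of individual readings
#'   around their lake-year annual mean (default 0.05). This is sampling
#'   noise within a summer; the lake's inter-annual residual SD `sigma` acts
#'   at the lake-year level and is what the trend model estimates.
#' @param contamination Named rates in `[0, 1]`: `feet`, `outlier`,
#'   `offseason`. Mutually exclusive per row; must sum to at most 1.
#' @param seed Integer seed; all stochastic stages derive their streams from
#'   it.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(n_lakes = 100, year_range = c(1938, 2012),
                          record_length_range = c(1, 34),
                          obs_per_summer = c(3, 12),
                          within_summer_sd = 0.05,
                          contamination = c(feet = 0, outlier = 0, offseason = 0),
                          seed = 1L) {
  stopifnot(n_lakes >= 1, length(year_range) == 2,
            year_range[1] <= year_range[2])
  rl <- as.integer(record_length_range)
  if (rl[1] < 1 || rl[2] > diff(year_range) + 1 || rl[1] > rl[2])
    stop("record_length_range must lie within [1, span of year_range]")
  contamination <- contamination[c("feet", "outlier", "offseason")]
  contamination[is.na(contamination)] <- 0
  names(contamination) <- c("feet", "outlier", "offseason")
  if (any(contamination < 0) || any(contamination > 1) || sum(contamination) > 1)
    stop("contamination rates must lie in [0,1] and sum to at most 1")
  if (within_summer_sd < 0) stop("within_summer_sd must be nonnegative")
  structure(list(n_lakes = as.integer(n_lakes), year_range = as.integer(year_range),
                 record_length_range = rl,
                 obs_per_summer = as.integer(obs_per_summer),
                 within_summer_sd = within_summer_sd,
                 contamination = contamination, seed = as.integer(seed)),
            class = "cohort_design")
}

#' Draw true lake-level parameters
#'
#' Draws, for each lake, its attributes (latitude, longitude, surface area),
#' monitoring window, and true log-scale intercept, slope and residual SD
#' from the hierarchical distributions. When `effects` is supplied the
#' lake means are linear in the standardized latitude covariate `z`;
#' otherwise they equal the population means in `hypers`.
#'
#' @param design A [cohort_design()].
#' @param hypers A [hyper_params()] (used when `effects` is `NULL`).
#' @param effects Optional [covariate_effects()].
#' @return Data frame with one row per lake: attributes, `z`, monitoring
#'   window (`start_year`, `end_year`), and truths `beta0`, `beta1`, `sigma`.
#' @export
draw_lake_parameters <- function(design, hypers = hyper_params(),
                                 effects = NULL) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(design$seed)
  J <- design$n_lakes
  lake_id <- sprintf("L%04d", seq_len(J))
  latitude <- stats::runif(J, 41, 49)   # Upper Midwest band
  longitude <- stats::runif(J, -97, -83)
  surface_area_ha <- 10^stats::rnorm(J, 1.7, 0.6)
  z <- if (J > 1) as.numeric(scale(latitude)) else 0

  len <- sample(design$record_length_range[1]:design$record_length_range[2],
                J, replace = TRUE)
  span <- design$year_range
  start_year <- span[1] +
    floor(stats::runif(J) * (span[2] - span[1] + 1 - len + 1))
  end_year <- start_year + len - 1L

  if (is.null(effects)) {
    m0 <- rep(hypers$mu_beta0, J); m1 <- rep(hypers$mu_beta1, J)
    mls <- rep(hypers$mu_logsigma, J)
    s0 <- hypers$sd_beta0; s1 <- hypers$sd_beta1; r <- hypers$rho
    sls <- hypers$sd_logsigma
  } else {
    stopifnot(inherits(effects, "covariate_effects"))
    m0 <- effects$g00 + effects$g01 * z
    m1 <- effects$g10 + effects$g11 * z
    mls <- effects$h0 + effects$h1 * z
    s0 <- effects$sd_beta0; s1 <- effects$sd_beta1; r <- effects$rho
    sls <- effects$sd_logsigma
  }
  # correlated bivariate normal deviations via Cholesky
  z0 <- stats::rnorm(J); z1 <- stats::rnorm(J)
  beta0 <- m0 + s0 * z0
  beta1 <- m1 + s1 * (r * z0 + sqrt(1 - r^2) * z1)
  sigma <- exp(mls + sls * stats::rnorm(J))
  data.frame(lake_id = lake_id, latitude = latitude, longitude = longitude,
             surface_area_ha = surface_area_ha, z = z,
             start_year = as.integer(start_year), end_year = as.integer(end_year),
             beta0 = beta0, beta1 = beta1, sigma = sigma,
             stringsAsFactors = FALSE)
}

#' Simulate a citizen observation table from true lake parameters
#'
#' For each lake-year in a lake's monitoring window, forms the true log-scale
#' annual mean `beta0 + beta1 * (year - center)` plus an inter-annual
#' deviation with the lake's residual SD `sigma` (the year covariate is
#' centered at the midpoint of the design's year range), then draws readings
#' around that annual mean with the design's within-summer SD, exponentiates
#' to meters, and stamps June-August dates. Clean readings are capped at the
#' 30 m regional plausibility ceiling so that only injected outliers exceed
#' it.
#' Contamination (feet-recorded rows, >30 m outliers, out-of-season dates) is
#' injected at the design's rates, mutually exclusively, with ground-truth
#' labels in the `contamination` attribute.
#'
#' @param params Output of [draw_lake_parameters()].
#' @param design The [cohort_design()].
#' @return List with `observations` (data frame: `lake_id`, `date`, `depth`,
#'   `unit`; attribute `contamination`), `attributes` (lake attribute table)
#'   and `center_year`.
#' @export
simulate_observations <- function(params, design) {
  stopifnot(inherits(design, "cohort_design"), nrow(params) >= 1)
  set.seed(design$seed + 1L)
  center <- mean(design$year_range)

  n_years <- params$end_year - params$start_year + 1L
  lake_rep <- rep(seq_len(nrow(params)), n_years)
  year <- unlist(mapply(seq, params$start_year, params$end_year,
                        SIMPLIFY = FALSE), use.names = FALSE)
  n_obs <- sample(design$obs_per_summer[1]:design$obs_per_summer[2],
                  length(year), replace = TRUE)
  row_lake <- rep(lake_rep, n_obs)
  row_year <- rep(year, n_obs)
  N <- length(row_lake)

  # one inter-annual deviation per lake-year; within-summer noise per reading
  mu_ly <- params$beta0[lake_rep] + params$beta1[lake_rep] * (year - center) +
    params$sigma[lake_rep] * stats::rnorm(length(year))
  mu_log <- rep(mu_ly, n_obs)
  depth <- exp(mu_log + design$within_summer_sd * stats::rnorm(N))
  depth <- pmin(depth, 30)  # regional plausibility ceiling for clean readings

  # June 1 .. Aug 31 = 92 calendar days
  day_offset <- floor(stats::runif(N) * 92)
  date <- as.Date(paste0(row_year, "-06-01")) + day_offset

  unit <- rep("m", N)
  rates <- design$contamination
  u <- stats::runif(N)
  type <- rep(NA_character_, N)
  type[u < rates["feet"]] <- "feet"
  type[u >= rates["feet"] & u < rates["feet"] + rates["outlier"]] <- "outlier"
  type[u >= rates["feet"] + rates["outlier"] &
         u < sum(rates)] <- "offseason"

  ft <- which(type == "feet")
  depth[ft] <- depth[ft] / 0.3048
  unit[ft] <- "ft"
  out <- which(type == "outlier")
  depth[out] <- stats::runif(length(out), 31, 45)
  off <- which(type == "offseason")
  if (length(off)) {
    month <- ifelse(stats::runif(length(off)) < 0.5, "05", "09")
    date[off] <- as.Date(paste0(row_year[off], "-", month, "-",
                                sprintf("%02d", 1 + floor(stats::runif(length(off)) * 28))))
  }

  obs <- data.frame(lake_id = params$lake_id[row_lake],
                    date = format(date, "%Y-%m-%d"),
                    depth = depth, unit = unit, stringsAsFactors = FALSE)
  attr(obs, "contamination") <-
    data.frame(row = which(!is.na(type)), type = type[!is.na(type)],
               stringsAsFactors = FALSE)
  attributes_tbl <- params[, c("lake_id", "latitude", "longitude",
                               "surface_area_ha")]
  list(observations = obs, attributes = attributes_tbl, center_year = center)
}

#' Generate a complete recovery bundle: truth plus simulated data
#'
#' Bundles the generating parameters, per-lake truths and the simulated
#' observation/attribute tables so model fits can be checked against known
#' ground truth. Regenerating with the same design reproduces the bundle
#' bit-for-bit.
#'
#' @inheritParams draw_lake_parameters
#' @return An object of class `secchi_truth_bundle`.
#' @export
make_recovery_bundle <- function(design, hypers = hyper_params(),
                                 effects = NULL) {
  params <- draw_lake_parameters(design, hypers, effects)
  sim <- simulate_observations(params, design)
  structure(list(design = design, hypers = hypers, effects = effects,
                 lake_params = params, observations = sim$observations,
                 attributes = sim$attributes, center_year = sim$center_year),
            class = "secchi_truth_bundle")
}

.write_num_csv <- function(df, path) {
  out <- df
  for (nm in names(out))
    if (is.double(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Persist a recovery bundle as CSV tables plus a JSON manifest
#'
#' @param bundle A `secchi_truth_bundle`.
#' @param dir Output directory (created if needed).
#' @export
save_truth_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "secchi_truth_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .write_num_csv(bundle$observations, file.path(dir, "observations.csv"))
  cont <- attr(bundle$observations, "contamination")
  utils::write.csv(cont, file.path(dir, "contamination.csv"), row.names = FALSE)
  .write_num_csv(bundle$attributes, file.path(dir, "attributes.csv"))
  .write_num_csv(bundle$lake_params, file.path(dir, "lake_params.csv"))
  design_out <- unclass(bundle$design)
  design_out$contamination <- as.list(design_out$contamination)  # keep names in JSON
  manifest <- list(design = design_out,
                   hypers = unclass(bundle$hypers),
                   effects = if (is.null(bundle$effects)) NULL else
                     unclass(bundle$effects),
                   center_year = bundle$center_year)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(dir)
}

#' Load a recovery bundle persisted by [save_truth_bundle()]
#'
#' @param dir Directory written by [save_truth_bundle()].
#' @export
load_truth_bundle <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  design <- do.call(cohort_design, c(manifest$design[
    c("n_lakes", "year_range", "record_length_range", "obs_per_summer",
      "within_summer_sd")],
    list(contamination = unlist(manifest$design$contamination),
         seed = manifest$design$seed)))
  hypers <- do.call(hyper_params, manifest$hypers)
  effects <- if (is.null(manifest$effects)) NULL else
    do.call(covariate_effects, manifest$effects)
  obs <- utils::read.csv(file.path(dir, "observations.csv"),
                         stringsAsFactors = FALSE,
                         colClasses = c(lake_id = "character", date = "character",
                                        depth = "numeric", unit = "character"))
  cont <- utils::read.csv(file.path(dir, "contamination.csv"),
                          stringsAsFactors = FALSE)
  attr(obs, "contamination") <- cont
  structure(list(design = design, hypers = hypers, effects = effects,
                 lake_params = utils::read.csv(file.path(dir, "lake_params.csv"),
                                               stringsAsFactors = FALSE),
                 observations = obs,
                 attributes = utils::read.csv(file.path(dir, "attributes.csv"),
                                              stringsAsFactors = FALSE),
                 center_year = manifest$center_year),
            class = "secchi_truth_bundle")
}

#' Run the QA/QC pipeline on a simulated observation table
#'
#' Convenience wrapper: writes nothing, feeds a simulated table through unit
#' conversion, the depth ceiling, and the summer window, and aggregates
#' retained rows to lake-year means.
#'
#' @param observations Data frame with columns `lake_id`, `date`, `depth`,
#'   `unit` (as emitted by [simulate_observations()]).
#' @return List with the flagged `secchi_obs` table (`obs`) and the lake-year
#'   table (`lake_years`).
#' @export
pipeline_from_table <- function(observations) {
  obs <- observation_table(observations$lake_id, observations$date,
                           observations$depth, observations$unit)
  obs <- convert_to_meters(obs)
  obs <- apply_depth_ceiling(obs)
  obs <- restrict_to_summer(obs)
  list(obs = obs, lake_years = aggregate_lake_years(obs))
}
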