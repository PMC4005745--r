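FEET_PER_METER <- 0.3048  # international foot, exact

.dispositions <- c("retained", "depth_ceiling_removed", "out_of_season_removed")

new_obs_table <- function(df, rejects = NULL) {
  stopifnot(all(c("lake_id", "obs_date", "depth", "unit",
                  "unit_converted", "disposition") %in% names(df)))
  structure(df, class = c("secchi_obs", "data.frame"),
            rejects = rejects %||% data.frame(line = integer(), reason = character()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read raw Secchi observation tables
#'
#' Reads a delimited text file of citizen Secchi readings and returns a
#' flagged observation table. Each usable row becomes one observation with a
#' `retained` disposition; rows that cannot be parsed (bad date, non-numeric
#' or non-positive depth, unknown unit) are counted and reported via the
#' `rejects` attribute rather than silently dropped.
#'
#' @param path Path to a delimited text file (CSV by default).
#' @param schema Named character vector mapping the canonical column names
#'   `lake_id`, `date`, `depth`, `unit` to the column names present in the
#'   file.
#' @param date_format Date pattern understood by [base::as.Date()]
#'   (default ISO-8601, `"%Y-%m-%d"`). No format sniffing is performed.
#' @param sep Field separator, default `","`.
#' @return A `secchi_obs` data frame with columns `lake_id`, `obs_date`,
#'   `depth`, `unit` (`"m"` or `"ft"`), `unit_converted` (logical) and
#'   `disposition`. Attribute `rejects` holds a data frame of rejected input
#'   lines with reasons.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(lake = "A", date = "2001-07-04", secchi = 2.5,
#'                      units = "m"), f, row.names = FALSE)
#' obs <- read_observations(f, schema = c(lake_id = "lake", date = "date",
#'                                        depth = "secchi", unit = "units"))
#' @export
read_observations <- function(path,
                              schema = c(lake_id = "lake_id", date = "date",
                                         depth = "depth", unit = "unit"),
                              date_format = "%Y-%m-%d",
                              sep = ",") {
  if (!file.exists(path)) stop("observation file not found: ", path)
  need <- c("lake_id", "date", "depth", "unit")
  if (!all(need %in% names(schema)))
    stop("schema must map all of: ", paste(need, collapse = ", "))
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  missing_cols <- setdiff(unname(schema[need]), names(raw))
  if (length(missing_cols))
    stop("mapped column(s) absent from file: ",
         paste(missing_cols, collapse = ", "))

  lake_id <- raw[[schema[["lake_id"]]]]
  dt <- as.Date(raw[[schema[["date"]]]], format = date_format)
  depth <- suppressWarnings(as.numeric(raw[[schema[["depth"]]]]))
  unit <- normalize_unit(raw[[schema[["unit"]]]])

  reason <- rep(NA_character_, nrow(raw))
  reason[is.na(dt)] <- "unparseable date"
  reason[is.na(depth)] <- "non-numeric depth"
  reason[!is.na(depth) & depth <= 0] <- "non-positive depth"
  reason[is.na(unit) & is.na(reason)] <- "unrecognized unit"
  bad <- !is.na(reason)
  rejects <- data.frame(line = which(bad) + 1L,  # +1 for the header line
                        reason = reason[bad], stringsAsFactors = FALSE)
  if (all(bad)) stop("no parseable observation rows in ", path)
  if (any(bad))
    message(sum(bad), " of ", nrow(raw), " rows rejected during ingest")

  ok <- !bad
  new_obs_table(data.frame(lake_id = lake_id[ok], obs_date = dt[ok],
                           depth = depth[ok], unit = unit[ok],
                           unit_converted = FALSE,
                           disposition = "retained",
                           stringsAsFactors = FALSE),
                rejects = rejects)
}

#' Construct an observation table in memory
#'
#' Builds a flagged `secchi_obs` table directly from vectors, for
#' programmatic use (the file-based entry point is [read_observations()]).
#' All rows start with a `retained` disposition.
#'
#' @param lake_id Character lake identifiers.
#' @param date Dates (`Date` or ISO-8601 strings).
#' @param depth Positive depths.
#' @param unit `"m"` or `"ft"` (aliases such as `"feet"` are recognized).
#' @export
observation_table <- function(lake_id, date, depth, unit = "m") {
  unit <- normalize_unit(rep_len(unit, length(lake_id)))
  if (anyNA(unit)) stop("unrecognized unit value(s)")
  if (any(!is.finite(depth) | depth <= 0)) stop("depths must be positive")
  new_obs_table(data.frame(lake_id = as.character(lake_id),
                           obs_date = as.Date(date), depth = as.numeric(depth),
                           unit = unit, unit_converted = FALSE,
                           disposition = "retained", stringsAsFactors = FALSE))
}

normalize_unit <- function(u) {
  u <- tolower(trimws(u))
  out <- rep(NA_character_, length(u))
  out[u %in% c("m", "meter", "meters", "metre", "metres")] <- "m"
  out[u %in% c("ft", "foot", "feet")] <- "ft"
  out
}

#' Convert all depth readings to meters
#'
#' Readings recorded in feet are multiplied by the exact international-foot
#' factor 0.3048 and flagged `unit_converted`; readings already in meters are
#' untouched.
#'
#' @param obs A `secchi_obs` table.
#' @return The table with every `depth` in meters and `unit == "m"`.
#' @export
convert_to_meters <- function(obs) {
  stopifnot(inherits(obs, "secchi_obs"))
  unit <- normalize_unit(obs$unit)
  if (anyNA(unit)) stop("unrecognized unit value(s): ",
                        paste(unique(obs$unit[is.na(unit)]), collapse = ", "))
  ft <- unit == "ft"
  obs$depth[ft] <- obs$depth[ft] * FEET_PER_METER
  obs$unit_converted <- obs$unit_converted | ft
  obs$unit <- "m"
  obs
}

#' Remove implausibly deep readings
#'
#' Flags readings strictly deeper than `ceiling_m` (default 30 m) as
#' `depth_ceiling_removed`; such values are treated as transcription errors.
#' A reading exactly at the ceiling is retained. Rows are flagged, never
#' deleted, so row counts are conserved.
#'
#' @param obs A `secchi_obs` table with depths in meters.
#' @param ceiling_m Positive ceiling in meters, default 30.
#' @export
apply_depth_ceiling <- function(obs, ceiling_m = 30) {
  stopifnot(inherits(obs, "secchi_obs"))
  if (!is.numeric(ceiling_m) || length(ceiling_m) != 1 || ceiling_m <= 0)
    stop("ceiling_m must be a single positive number")
  if (any(obs$unit != "m")) stop("depths must be in meters; run convert_to_meters() first")
  hit <- obs$disposition == "retained" & obs$depth > ceiling_m
  obs$disposition[hit] <- "depth_ceiling_removed"
  obs
}

#' Restrict observations to the summer index period
#'
#' Flags readings collected outside the June-August window (months 6-8,
#' inclusive of June 1 and August 31) as `out_of_season_removed`.
#'
#' @param obs A `secchi_obs` table.
#' @param months Integer months to keep, default `6:8`.
#' @export
restrict_to_summer <- function(obs, months = 6:8) {
  stopifnot(inherits(obs, "secchi_obs"))
  if (length(months) == 0) stop("months must be non-empty")
  m <- as.integer(format(obs$obs_date, "%m"))
  hit <- obs$disposition == "retained" & !(m %in% months)
  obs$disposition[hit] <- "out_of_season_removed"
  obs
}

#' Aggregate retained observations to lake-year summer means
#'
#' The response for all downstream modeling: the arithmetic mean of the
#' retained raw (untransformed, meter-scale) depths for each lake and summer.
#'
#' @param obs A `secchi_obs` table (depths in meters).
#' @return A data frame with one row per (lake, year): `lake_id`, `year`,
#'   `mean_secchi_m`, `n_obs`, ordered by lake then year.
#' @export
aggregate_lake_years <- function(obs) {
  stopifnot(inherits(obs, "secchi_obs"))
  keep <- obs[obs$disposition == "retained", , drop = FALSE]
  if (nrow(keep) == 0) stop("no retained observations to aggregate")
  year <- as.integer(format(keep$obs_date, "%Y"))
  key <- paste(keep$lake_id, year, sep = "\r")
  mean_m <- tapply(keep$depth, key, mean)
  n <- tapply(keep$depth, key, length)
  parts <- do.call(rbind, strsplit(names(mean_m), "\r", fixed = TRUE))
  out <- data.frame(lake_id = parts[, 1], year = as.integer(parts[, 2]),
                    mean_secchi_m = as.numeric(mean_m),
                    n_obs = as.integer(n), stringsAsFactors = FALSE)
  out <- out[order(out$lake_id, out$year), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Derive lake-level covariates from the monitoring record
#'
#' For each lake: latitude and (transformed) surface area from the attribute
#' table, the median sample date (the median of the calendar years possessing
#' a lake-year record; with an even count, the midpoint of the two central
#' years), and the record length `max(year) - min(year) + 1`. Surface area is
#' log10-transformed by default because lake areas span orders of magnitude.
#'
#' @param ly Lake-year table from [aggregate_lake_years()].
#' @param attrs Data frame with columns `lake_id`, `latitude`, `longitude`,
#'   `surface_area_ha` (one row per lake).
#' @param area_transform `"log10"` (default) or `"raw"`.
#' @return Data frame with one row per lake: `lake_id`, `latitude`,
#'   `surface_area`, `median_sample_date`, `record_length_years`.
#' @export
derive_lake_covariates <- function(ly, attrs, area_transform = c("log10", "raw")) {
  area_transform <- match.arg(area_transform)
  stopifnot(all(c("lake_id", "year") %in% names(ly)),
            all(c("lake_id", "latitude", "surface_area_ha") %in% names(attrs)))
  if (anyDuplicated(attrs$lake_id)) stop("attrs must have one row per lake_id")
  lakes <- sort(unique(ly$lake_id))
  miss <- setdiff(lakes, attrs$lake_id)
  if (length(miss)) stop("lake(s) missing from attribute table: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  idx <- match(lakes, attrs$lake_id)
  med <- vapply(lakes, function(l) {
    yrs <- unique(ly$year[ly$lake_id == l])
    stats::median(yrs)
  }, numeric(1))
  len <- vapply(lakes, function(l) {
    yrs <- ly$year[ly$lake_id == l]
    as.integer(max(yrs) - min(yrs) + 1L)
  }, integer(1))
  area <- attrs$surface_area_ha[idx]
  if (any(area <= 0)) stop("surface_area_ha must be positive")
  data.frame(lake_id = lakes,
             latitude = attrs$latitude[idx],
             surface_area = if (area_transform == "log10") log10(area) else area,
             median_sample_date = med,
             record_length_years = len,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Standardize lake-level covariates
#'
#' Centers and scales each named covariate to sample mean 0 and sample SD 1
#' across the modeled lake set, appending a `<name>_z` column. The `(center,
#' scale)` pairs are stored in the `standardization` attribute so the
#' transform is exactly invertible.
#'
#' @param cov Covariate table from [derive_lake_covariates()].
#' @param which Character vector of covariate column names to standardize.
#' @export
standardize_covariates <- function(cov,
                                   which = c("latitude", "surface_area",
                                             "median_sample_date")) {
  stopifnot(is.data.frame(cov), all(which %in% names(cov)))
  params <- attr(cov, "standardization") %||% list()
  for (nm in which) {
    x <- cov[[nm]]
    ctr <- mean(x)
    scl <- stats::sd(x)
    if (!is.finite(scl) || scl == 0)
      stop("covariate '", nm, "' is constant (zero SD); cannot standardize")
    cov[[paste0(nm, "_z")]] <- (x - ctr) / scl
    params[[nm]] <- c(center = ctr, scale = scl)
  }
  attr(cov, "standardization") <- params
  cov
}

#' Invert covariate standardization
#'
#' @param z Standardized values.
#' @param cov Table carrying a `standardization` attribute.
#' @param name Covariate name.
#' @export
unstandardize <- function(z, cov, name) {
  p <- attr(cov, "standardization")[[name]]
  if (is.null(p)) stop("no standardization parameters stored for '", name, "'")
  z * p[["scale"]] + p[["center"]]
}

#' Summarize QA/QC dispositions
#'
#' Counts rows per terminal disposition, unit conversions, and ingest
#' rejects. All filters flag rather than delete, so these counts account for
#' every input row.
#'
#' @param obs A `secchi_obs` table after filtering.
#' @return A list with `n_rows`, `retained`, `depth_ceiling_removed`,
#'   `out_of_season_removed`, `unit_converted` and `ingest_rejects`.
#' @export
qaqc_summary <- function(obs) {
  stopifnot(inherits(obs, "secchi_obs"))
  disp <- table(factor(obs$disposition, levels = .dispositions))
  list(n_rows = nrow(obs),
       retained = unname(disp[["retained"]]),
       depth_ceiling_removed = unname(disp[["depth_ceiling_removed"]]),
       out_of_season_removed = unname(disp[["out_of_season_removed"]]),
       unit_converted = sum(obs$unit_converted),
       ingest_rejects = nrow(attr(obs, "rejects") %||% data.frame()))
}
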