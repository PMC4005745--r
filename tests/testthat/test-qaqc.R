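write_obs_csv <- function(df, schema_names = c("lake", "date", "secchi", "units")) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  names(df) <- schema_names
  utils::write.csv(df, path, row.names = FALSE)
  path
}

schema <- c(lake_id = "lake", date = "date", depth = "secchi", unit = "units")

test_that("ingest returns one observation per parseable row and reports rejects", {
  df <- data.frame(l = c("A", "A", "B"), d = c("2001-07-01", "2001-07-15", "2002-06-20"),
                   s = c("2.1", "2.5", "3.0"), u = "m")
  p <- write_obs_csv(df)
  obs <- read_observations(p, schema)
  expect_s3_class(obs, "secchi_obs")
  expect_equal(nrow(obs), 3)
  expect_equal(nrow(attr(obs, "rejects")), 0)
  expect_true(all(obs$disposition == "retained"))

  df_bad <- rbind(df, data.frame(l = "C", d = "2003-07-07", s = "deep", u = "m"))
  p2 <- write_obs_csv(df_bad)
  expect_message(obs2 <- read_observations(p2, schema), "1 of 4 rows rejected")
  expect_equal(nrow(obs2), 3)
  expect_equal(attr(obs2, "rejects")$reason, "non-numeric depth")
})

test_that("ingest preconditions are enforced", {
  expect_error(read_observations(tempfile(), schema), "not found")
  df <- data.frame(l = "A", d = "2001-07-01", s = "2.1", u = "m")
  p <- write_obs_csv(df)
  bad_schema <- schema; bad_schema[["depth"]] <- "no_such_column"
  expect_error(read_observations(p, bad_schema), "absent from file")
  all_bad <- write_obs_csv(data.frame(l = "A", d = "not a date", s = "2", u = "m"))
  expect_error(suppressMessages(read_observations(all_bad, schema)),
               "no parseable")
})

test_that("unit conversion uses the exact foot factor and flags converted rows", {
  obs <- observation_table(c("A", "B"), c("2001-07-01", "2001-07-02"),
                           c(10, 2.5), c("ft", "m"))
  out <- convert_to_meters(obs)
  expect_identical(out$depth, c(10 * 0.3048, 2.5))
  expect_identical(out$unit_converted, c(TRUE, FALSE))
  expect_true(all(out$unit == "m"))
  expect_equal(sum(out$unit_converted), 1)
  obs$unit[1] <- "fathoms"
  expect_error(convert_to_meters(obs), "unrecognized unit")
})

test_that("depth ceiling removes strictly deeper readings and keeps the boundary", {
  obs <- observation_table("A", rep("2001-07-01", 4), c(30.0, 2.1, 31.5, 29.9))
  out <- apply_depth_ceiling(obs, 30)
  expect_equal(out$disposition,
               c("retained", "retained", "depth_ceiling_removed", "retained"))
  expect_error(apply_depth_ceiling(obs, -1), "positive")
  # empty table passes through
  empty <- obs[0, , drop = FALSE]
  expect_equal(nrow(apply_depth_ceiling(empty)), 0)
})

test_that("summer window keeps June 1 and August 31 and drops other months", {
  obs <- observation_table("A", c("1999-06-01", "1999-05-31", "2000-08-31",
                                  "2000-09-01"), 2)
  out <- restrict_to_summer(obs)
  expect_equal(out$disposition, c("retained", "out_of_season_removed",
                                  "retained", "out_of_season_removed"))
  expect_error(restrict_to_summer(obs, integer()), "non-empty")
})

test_that("filters conserve rows, are idempotent, and flag rather than drop", {
  set.seed(5)
  n <- 200
  obs <- observation_table(sample(LETTERS[1:4], n, TRUE),
                           as.Date("2000-01-01") + sample.int(3650, n, TRUE),
                           exp(rnorm(n, 1, 1.2)))
  f1 <- restrict_to_summer(apply_depth_ceiling(obs))
  expect_equal(nrow(f1), n)
  counts <- qaqc_summary(f1)
  expect_equal(counts$retained + counts$depth_ceiling_removed +
                 counts$out_of_season_removed, n)
  f2 <- restrict_to_summer(apply_depth_ceiling(f1))
  expect_identical(f1, f2)
})

test_that("lake-year aggregation computes raw-scale means and conserves counts", {
  obs <- observation_table("L1", c("2001-06-10", "2001-07-10", "2001-08-10"),
                           c(2, 3, 4))
  ly <- aggregate_lake_years(obs)
  expect_equal(ly$mean_secchi_m, 3)
  expect_equal(ly$n_obs, 3L)

  single <- aggregate_lake_years(observation_table("L1", "2001-07-01", 1.7))
  expect_equal(single$mean_secchi_m, 1.7)
  expect_equal(single$n_obs, 1L)

  obs2 <- observation_table(c("A", "A", "A", "A", "B", "B", "B"),
                            c("2001-07-01", "2001-07-08", "2002-07-01",
                              "2002-08-01", "2001-06-15", "2001-06-20",
                              "2002-07-04"),
                            c(1, 2, 3, 4, 5, 6, 7))
  ly2 <- aggregate_lake_years(obs2)
  expect_equal(nrow(ly2), 4)
  expect_equal(sum(ly2$n_obs), 7)
  # order invariance
  perm <- obs2[sample(nrow(obs2)), , drop = FALSE]
  expect_equal(aggregate_lake_years(perm), ly2)
  # removed rows do not contribute
  flagged <- apply_depth_ceiling(observation_table("A", rep("2001-07-01", 2),
                                                   c(2, 40)))
  expect_equal(aggregate_lake_years(flagged)$n_obs, 1L)
  expect_error(aggregate_lake_years(flagged[flagged$depth > 30, ]),
               "no retained")
})

test_that("lake covariates: median record year, record length, area transform", {
  ly <- data.frame(lake_id = rep(c("A", "B", "C"),
                                 times = c(21, 1, 2)),
                   year = c(1980:2000, 1995, 1990, 2000),
                   mean_secchi_m = 2, n_obs = 1L)
  attrs <- data.frame(lake_id = c("A", "B", "C"), latitude = c(45, 46, 47),
                      longitude = -93, surface_area_ha = c(100, 10, 1000))
  cov <- derive_lake_covariates(ly, attrs)
  expect_equal(cov$median_sample_date, c(1990, 1995, 1995))
  expect_equal(cov$record_length_years, c(21L, 1L, 11L))
  expect_equal(cov$surface_area, c(2, 1, 3))  # log10 default
  raw <- derive_lake_covariates(ly, attrs, area_transform = "raw")
  expect_equal(raw$surface_area, c(100, 10, 1000))
  expect_error(derive_lake_covariates(ly, attrs[-2, ]), "missing from attribute")
})

test_that("covariate standardization is exact and invertible", {
  cov <- data.frame(lake_id = c("A", "B", "C"), latitude = c(1, 2, 3),
                    surface_area = c(5, 5, 5), median_sample_date = c(1970, 1990, 2010))
  out <- standardize_covariates(cov, "latitude")
  expect_equal(out$latitude_z, c(-1, 0, 1))
  expect_equal(mean(out$latitude_z), 0, tolerance = 1e-12)
  expect_equal(sd(out$latitude_z), 1, tolerance = 1e-12)
  expect_error(standardize_covariates(cov, "surface_area"), "constant")

  set.seed(2)
  cov2 <- data.frame(lake_id = letters[1:20], latitude = runif(20, 40, 50))
  s <- standardize_covariates(cov2, "latitude")
  back <- unstandardize(s$latitude_z, s, "latitude")
  expect_lt(max(abs(back - cov2$latitude)), 1e-9)
})
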