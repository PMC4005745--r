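test_that("model data takes logs and centers the year covariate", {
  ly <- data.frame(lake_id = "A", year = 1980:2000,
                   mean_secchi_m = c(1.0, rep(2.4, 20)))
  md <- build_model_data(ly)
  expect_equal(md$y[1], 0)
  expect_equal(md$y[2], log(2.4))
  expect_equal(round(md$y[2], 4), 0.8755)
  expect_equal(sum(md$x), 0)
  expect_equal(md$center_year, 1990)
  expect_error(build_model_data(transform(ly, mean_secchi_m = 0)), "positive")
  expect_error(build_model_data(ly, covariate_name = "latitude_z"),
               "not found")
})

test_that("single-lake known-variance posterior matches the conjugate closed form", {
  set.seed(21)
  years <- 2001:2012
  x <- years - mean(years)
  sig <- 0.3
  y <- 1 + 0.02 * x + rnorm(length(x), 0, sig)
  ly <- data.frame(lake_id = "A", year = years, mean_secchi_m = exp(y))
  md <- build_model_data(ly)
  prior_cov <- diag(c(100, 1))
  oracle <- conjugate_blr(cbind(1, x), y, sig, c(0, 0), prior_cov)
  f <- fit_unconditional(
    md, settings = mcmc_settings(2, 500, 1, 8000, seed = 22),
    fixed = list(sigma = sig, mu_beta = c(0, 0), sd_beta0 = 10, sd_beta1 = 1,
                 rho = 0, mu_logsigma = log(sig), sd_logsigma = 0.1))
  for (k in 1:2) {
    p <- c("beta0[A]", "beta1[A]")[k]
    d <- pooled_draws(f, p)
    expect_lt(abs(mean(d) - oracle$mean[k]), 3 * mcse_mean(d))
    # MC error of a posterior SD estimate, normal approximation
    expect_lt(abs(sd(d) - oracle$sd[k]), 3 * oracle$sd[k] / sqrt(2 * length(d) / 10))
  }
})

test_that("two-lake sampler marginals match dense grid quadrature", {
  sig <- 0.25; sd0 <- 0.6; sd1 <- 0.05; rho <- 0.3
  yrs <- 2001:2004
  ly <- data.frame(lake_id = rep(c("A", "B"), each = 4), year = rep(yrs, 2),
                   mean_secchi_m = exp(c(0.4, 0.5, 0.6, 0.8,
                                         1.2, 1.1, 1.0, 0.9)))
  md <- build_model_data(ly, center_year = mean(yrs))
  oracle <- grid_oracle_two_lakes(ly, sig, sd0, sd1, rho, mean(yrs),
                                  mu0_range = c(-1.5, 2.5),
                                  mu1_range = c(-0.6, 0.6), n_grid = 301)
  f <- fit_unconditional(md, settings = mcmc_settings(3, 1500, 1, 45000, seed = 23),
                         fixed = list(sigma = sig, sd_beta0 = sd0,
                                      sd_beta1 = sd1, rho = rho))
  expect_lt(abs(mean(pooled_draws(f, "mu_beta0")) - oracle$mu[1]), 0.02)
  expect_lt(abs(mean(pooled_draws(f, "mu_beta1")) - oracle$mu[2]), 0.02)
  for (l in c("A", "B")) {
    expect_lt(abs(mean(pooled_draws(f, paste0("beta0[", l, "]"))) -
                    oracle$beta[[l]][1]), 0.02)
    expect_lt(abs(mean(pooled_draws(f, paste0("beta1[", l, "]"))) -
                    oracle$beta[[l]][2]), 0.02)
  }
})

test_that("the reflected Metropolis update for rho matches 1-D quadrature", {
  set.seed(24)
  sig <- 0.2; sd0 <- 0.5; sd1 <- 0.1; mu <- c(0.8, 0.05)
  yrs <- 2001:2005
  mk <- function(b0, b1) exp(b0 + b1 * (yrs - mean(yrs)) + rnorm(5, 0, sig))
  ly <- data.frame(lake_id = rep(c("A", "B", "C", "D"), each = 5),
                   year = rep(yrs, 4),
                   mean_secchi_m = c(mk(0.3, 0.1), mk(1.2, 0.0),
                                     mk(0.7, -0.05), mk(1.0, 0.12)))
  oracle_rho <- grid_oracle_rho(ly, sig, sd0, sd1, mu, mean(yrs))
  md <- build_model_data(ly, center_year = mean(yrs))
  f <- fit_unconditional(md, settings = mcmc_settings(3, 2000, 1, 45000, seed = 25),
                         fixed = list(sigma = sig, mu_beta = mu,
                                      sd_beta0 = sd0, sd_beta1 = sd1))
  expect_lt(abs(mean(pooled_draws(f, "rho")) - oracle_rho), 0.02)
})

test_that("near-zero group SDs pool lake estimates toward common values", {
  d <- cohort_design(n_lakes = 30, seed = 26)
  hy <- hyper_params(sd_beta0 = 1e-4, sd_beta1 = 1e-6, rho = 0)
  b <- make_recovery_bundle(d, hy)
  pl <- pipeline_from_table(b$observations)
  md <- build_model_data(pl$lake_years, center_year = b$center_year)
  f <- fit_unconditional(md, settings = mcmc_settings(2, 600, 1, 2000, seed = 27))
  b1 <- sapply(b$lake_params$lake_id, function(l)
    mean(pooled_draws(f, paste0("beta1[", l, "]"))))
  # spread of lake slope estimates collapses far below the data-level spread
  expect_lt(sd(b1), 0.002)
})

test_that("draws respect parameter supports", {
  b <- make_recovery_bundle(cohort_design(n_lakes = 12, seed = 28))
  md <- build_model_data(pipeline_from_table(b$observations)$lake_years,
                         center_year = b$center_year)
  f <- fit_unconditional(md, settings = mcmc_settings(2, 300, 1, 1000, seed = 29))
  all_draws <- do.call(rbind, f$draws)
  expect_true(all(all_draws[, grepl("^sigma\\[", colnames(all_draws))] > 0))
  expect_true(all(abs(all_draws[, "rho"]) < 1))
  for (p in c("sd_beta0", "sd_beta1", "sd_logsigma"))
    expect_true(all(all_draws[, p] >= 0 & all_draws[, p] <= 100))
})

test_that("fits are deterministic given data, settings and seed", {
  b <- make_recovery_bundle(cohort_design(n_lakes = 8, seed = 30))
  ly <- pipeline_from_table(b$observations)$lake_years
  md <- build_model_data(ly, center_year = b$center_year)
  st <- mcmc_settings(2, 200, 2, 600, seed = 31)
  f1 <- fit_unconditional(md, settings = st)
  f2 <- fit_unconditional(md, settings = st)
  expect_identical(f1$draws, f2$draws)
  # row order of the lake-year table is irrelevant
  md_perm <- build_model_data(ly[sample(nrow(ly)), ], center_year = b$center_year)
  f3 <- fit_unconditional(md_perm, settings = st)
  expect_identical(f1$draws, f3$draws)
})

test_that("model preconditions are enforced", {
  ly <- data.frame(lake_id = "A", year = 2001:2005, mean_secchi_m = 2)
  expect_error(fit_unconditional(build_model_data(ly)), ">= 2 lakes")
  ly2 <- data.frame(lake_id = rep(c("A", "B", "C"), each = 3),
                    year = rep(2001:2003, 3), mean_secchi_m = 2)
  md2 <- build_model_data(ly2)
  expect_error(fit_with_covariate(md2), "no covariate")
  cov <- data.frame(lake_id = c("A", "B", "C"), latitude_z = c(1, 1, 1))
  md3 <- build_model_data(ly2, cov, "latitude_z")
  expect_error(fit_with_covariate(md3), "distinct covariate")
  expect_error(mcmc_settings(thin = 0))
})

test_that("scale reduction factor matches hand computation and i.i.d. behavior", {
  expect_equal(gelman_rubin(list(c(1, 2), c(3, 4))), sqrt(4.5))
  set.seed(32)
  chains <- list(rnorm(5000), rnorm(5000), rnorm(5000))
  r <- gelman_rubin(chains)
  expect_gte(r, 0.99); expect_lte(r, 1.05)
  expect_error(gelman_rubin(list(c(1, 2))), "2 chains")
  expect_error(gelman_rubin(list(c(1, 1), c(1, 1))), "zero within-chain")
})

test_that("scale reduction agrees with the coda implementation on long chains", {
  set.seed(33)
  chains <- list(rnorm(4000), rnorm(4000, 0.05))
  ours <- gelman_rubin(chains)
  ref <- unname(coda::gelman.diag(coda::mcmc.list(lapply(chains, coda::mcmc)),
                                  autoburnin = FALSE)$psrf[1, 1])
  expect_equal(ours, ref, tolerance = 0.01)
})
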