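#' Assemble model data from a lake-year table
#'
#' Builds the response and design for the hierarchical trend model: the
#' response is the natural log of the lake-year summer mean depth, and the
#' year covariate is centered (mean-subtracted) so the slope keeps per-year
#' units and the intercept is interpretable at the average year. Lakes with a
#' single year are retained; their slopes are informed by pooling.
#'
#' @param ly Lake-year table from [aggregate_lake_years()] (columns
#'   `lake_id`, `year`, `mean_secchi_m`).
#' @param covariates Optional covariate table from
#'   [standardize_covariates()].
#' @param covariate_name Optional name of one standardized covariate column
#'   (e.g. `"latitude_z"`) to attach for the covariate model.
#' @param center_year Centering constant for the year covariate; defaults to
#'   the grand mean year over lake-year rows.
#' @return An object of class `secchi_model_data`.
#' @export
build_model_data <- function(ly, covariates = NULL, covariate_name = NULL,
                             center_year = NULL) {
  stopifnot(all(c("lake_id", "year", "mean_secchi_m") %in% names(ly)))
  if (any(ly$mean_secchi_m <= 0))
    stop("all mean_secchi_m must be positive to take logs")
  lakes <- sort(unique(ly$lake_id))
  j <- match(ly$lake_id, lakes)
  center <- center_year %||% mean(ly$year)
  z <- NULL
  if (!is.null(covariate_name)) {
    if (is.null(covariates) || !covariate_name %in% names(covariates))
      stop("covariate '", covariate_name, "' not found in covariate table")
    idx <- match(lakes, covariates$lake_id)
    if (anyNA(idx)) stop("covariate table is missing modeled lakes")
    z <- covariates[[covariate_name]][idx]
  }
  # canonical row order: results are invariant to input row permutations,
  # bit-for-bit (summation order in the sufficient statistics is fixed)
  ord <- order(j, ly$year)
  j <- j[ord]
  structure(list(y = log(ly$mean_secchi_m)[ord],
                 x = (ly$year - center)[ord],
                 j = j, lake_ids = lakes, J = length(lakes),
                 n = nrow(ly), center_year = center,
                 z = z, covariate_name = covariate_name),
            class = "secchi_model_data")
}

#' Prior specification
#'
#' Non-informative priors: normal with a large variance for location
#' parameters, uniform on `[0, sd_upper]` for scale (SD) parameters, uniform
#' on `[-1, 1]` for the intercept-slope correlation.
#'
#' @param location_var Prior variance of location parameters (default `1e6`).
#' @param sd_upper Upper bound of the uniform prior on SDs (default 100).
#' @export
prior_spec <- function(location_var = 1e6, sd_upper = 100) {
  stopifnot(location_var > 0, sd_upper > 0)
  structure(list(location_var = location_var, sd_upper = sd_upper,
                 rho_bounds = c(-1, 1)), class = "prior_spec")
}

#' MCMC sampler settings
#'
#' Defaults mirror a three-chain protocol with 10,000 burn-in iterations and
#' every 3rd subsequent draw retained until 20,000 draws are kept in total
#' across chains. Proposal scales for the non-conjugate (Metropolis) updates
#' are adapted during burn-in only and frozen afterwards, which preserves the
#' correct stationary distribution.
#'
#' @param n_chains Number of parallel chains (default 3).
#' @param burn_in Discarded iterations per chain (default 10000).
#' @param thin Keep every `thin`-th post-burn-in draw (default 3).
#' @param n_retained_total Total retained draws across chains (default
#'   20000).
#' @param seed Integer seed; chain-specific streams are derived from it.
#' @param adapt Adapt Metropolis proposal scales during burn-in.
#' @export
mcmc_settings <- function(n_chains = 3, burn_in = 10000, thin = 3,
                          n_retained_total = 20000, seed = 1L, adapt = TRUE) {
  stopifnot(n_chains >= 1, burn_in >= 0, thin >= 1, n_retained_total >= 1)
  structure(list(n_chains = as.integer(n_chains), burn_in = as.integer(burn_in),
                 thin = as.integer(thin),
                 n_retained_total = as.integer(n_retained_total),
                 seed = as.integer(seed), adapt = isTRUE(adapt)),
            class = "mcmc_settings")
}

# Per-lake sufficient statistics of the lake-year regression
.suff_stats <- function(md) {
  j <- md$j
  list(n = as.numeric(tabulate(j, md$J)),
       Sx = as.numeric(rowsum(md$x, j)),
       Sxx = as.numeric(rowsum(md$x^2, j)),
       Sy = as.numeric(rowsum(md$y, j)),
       Sxy = as.numeric(rowsum(md$x * md$y, j)),
       Syy = as.numeric(rowsum(md$y^2, j)))
}

# Fold a proposal back into [lo, hi] (reflection keeps the proposal symmetric)
.reflect <- function(p, lo, hi) {
  w <- hi - lo
  p <- (p - lo) %% (2 * w)
  lo + ifelse(p > w, 2 * w - p, p)
}

# log joint density of second-stage intercept/slope deviations under
# SDs (s0, s1) and correlation r, from sufficient stats of the deviations
.ll_bvn <- function(s0, s1, r, S00, S01, S11, J) {
  if (s0 <= 0 || s1 <= 0 || r <= -1 || r >= 1) return(-Inf)
  q <- S00 / s0^2 - 2 * r * S01 / (s0 * s1) + S11 / s1^2
  -J * (log(s0) + log(s1) + 0.5 * log1p(-r^2)) - q / (2 * (1 - r^2))
}

# Draw from a bivariate normal given 2x2 precision A and rhs b (mean solves
# A m = b); returns c(draw1, draw2)
.draw_mvn2 <- function(A, b) {
  U <- chol(A)
  m <- backsolve(U, backsolve(U, b, transpose = TRUE))
  m + backsolve(U, stats::rnorm(2))
}

.run_chain <- function(ss, md, priors, model, fixed, n_iter, burn, thin,
                       n_keep, chain, chain_seed) {
  set.seed(chain_seed)
  J <- md$J
  V0 <- priors$location_var
  sd_hi <- priors$sd_upper
  z <- md$z
  covariate <- identical(model, "covariate")

  # --- empirical starting values: per-lake least squares, chain-jittered ---
  n <- ss$n
  denom <- ss$Sxx - ss$Sx^2 / n
  pool_b1 <- {
    nx <- md$n
    d <- sum(md$x^2) - sum(md$x)^2 / nx
    if (d > 1e-10) (sum(md$x * md$y) - sum(md$x) * sum(md$y) / nx) / d else 0
  }
  b1hat <- ifelse(denom > 1e-10, (ss$Sxy - ss$Sx * ss$Sy / n) / denom, pool_b1)
  b0hat <- (ss$Sy - b1hat * ss$Sx) / n
  ssr0 <- pmax(ss$Syy - 2 * b0hat * ss$Sy - 2 * b1hat * ss$Sxy +
                 n * b0hat^2 + 2 * b0hat * b1hat * ss$Sx + b1hat^2 * ss$Sxx, 0)
  sig_hat <- sqrt(ifelse(n > 2, ssr0 / pmax(n - 2, 1), NA))
  sig_hat[!is.finite(sig_hat) | sig_hat < 1e-3] <-
    max(stats::median(sig_hat[is.finite(sig_hat) & sig_hat >= 1e-3], na.rm = TRUE),
        0.05, na.rm = TRUE)

  jit <- chain  # over-dispersed: later chains start farther out
  beta0 <- b0hat + stats::rnorm(J, 0, 0.05 * jit)
  beta1 <- b1hat + stats::rnorm(J, 0, 0.003 * jit)

  sigma_fixed <- !is.null(fixed$sigma)
  if (sigma_fixed) {
    ls <- log(rep_len(fixed$sigma, J))
  } else {
    ls <- log(sig_hat) + stats::rnorm(J, 0, 0.1 * jit)
  }

  mu_fixed <- !is.null(fixed$mu_beta)
  if (covariate) {
    gam <- c(mean(beta0), 0, mean(beta1), 0) +
      stats::rnorm(4, 0, c(0.05, 0.02, 0.003, 0.002) * jit)  # (g00,g01,g10,g11)
    hvec <- c(mean(ls), 0) + stats::rnorm(2, 0, c(0.1, 0.05) * jit)
  } else {
    mu <- if (mu_fixed) fixed$mu_beta else
      c(mean(beta0), mean(beta1)) + stats::rnorm(2, 0, c(0.05, 0.003) * jit)
    mls <- if (!is.null(fixed$mu_logsigma)) fixed$mu_logsigma else
      mean(ls) + stats::rnorm(1, 0, 0.1 * jit)
  }
  clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)
  sd0 <- if (!is.null(fixed$sd_beta0)) fixed$sd_beta0 else
    clamp(stats::sd(b0hat) * exp(stats::rnorm(1, 0, 0.2 * jit)), 0.01, sd_hi - 1e-6)
  sd1 <- if (!is.null(fixed$sd_beta1)) fixed$sd_beta1 else
    clamp(max(stats::sd(b1hat), 1e-3) * exp(stats::rnorm(1, 0, 0.2 * jit)),
          1e-4, sd_hi - 1e-6)
  rho <- if (!is.null(fixed$rho)) fixed$rho else
    clamp(suppressWarnings(stats::cor(b0hat, b1hat)) + stats::rnorm(1, 0, 0.1 * jit),
          -0.9, 0.9)
  if (!is.finite(rho)) rho <- 0
  sls <- if (!is.null(fixed$sd_logsigma)) fixed$sd_logsigma else
    clamp(0.5 * exp(stats::rnorm(1, 0, 0.2 * jit)), 0.01, sd_hi - 1e-6)

  sd0_fixed <- !is.null(fixed$sd_beta0); sd1_fixed <- !is.null(fixed$sd_beta1)
  rho_fixed <- !is.null(fixed$rho); sls_fixed <- !is.null(fixed$sd_logsigma)
  mls_fixed <- !is.null(fixed$mu_logsigma)

  # Metropolis proposal scales (adapted during burn-in, frozen after)
  step_ls <- rep(0.5, J)
  step_sd0 <- 0.1; step_sd1 <- 0.01; step_rho <- 0.1; step_sls <- 0.1
  acc_ls <- numeric(J); acc_sd0 <- 0; acc_sd1 <- 0; acc_rho <- 0; acc_sls <- 0
  acc_ls_tot <- numeric(J); acc_sc_tot <- c(sd0 = 0, sd1 = 0, rho = 0, sls = 0)
  adapt_every <- 50L

  if (covariate) {
    Zt1 <- J; Ztz <- sum(z); Zzz <- sum(z^2)
    ZtZ <- matrix(c(Zt1, Ztz, Ztz, Zzz), 2, 2)
  }

  pop_names <- if (covariate)
    c("g00", "g01", "g10", "g11", "sd_beta0", "sd_beta1", "rho",
      "h0", "h1", "sd_logsigma")
  else
    c("mu_beta0", "mu_beta1", "sd_beta0", "sd_beta1", "rho",
      "mu_logsigma", "sd_logsigma")
  cn <- c(pop_names,
          paste0("beta0[", md$lake_ids, "]"),
          paste0("beta1[", md$lake_ids, "]"),
          paste0("sigma[", md$lake_ids, "]"))
  out <- matrix(NA_real_, n_keep, length(cn), dimnames = list(NULL, cn))
  keep_i <- 0L

  for (it in seq_len(n_iter)) {
    adapting <- it <= burn

    # prior means of (beta0_j, beta1_j) and of log sigma_j
    if (covariate) {
      pm0 <- gam[1] + gam[2] * z   # note gam = (g00, g01, g10, g11)
      pm1 <- gam[3] + gam[4] * z
      mls_j <- hvec[1] + hvec[2] * z
    } else {
      pm0 <- rep(mu[1], J); pm1 <- rep(mu[2], J)
      mls_j <- rep(mls, J)
    }

    # --- (beta0_j, beta1_j): conjugate bivariate-normal updates ---
    om <- 1 / (1 - rho^2)
    Q11 <- om / sd0^2; Q22 <- om / sd1^2; Q12 <- -rho * om / (sd0 * sd1)
    s2i <- exp(-2 * ls)
    P11 <- ss$n * s2i + Q11
    P12 <- ss$Sx * s2i + Q12
    P22 <- ss$Sxx * s2i + Q22
    r1 <- ss$Sy * s2i + Q11 * pm0 + Q12 * pm1
    r2 <- ss$Sxy * s2i + Q12 * pm0 + Q22 * pm1
    det <- P11 * P22 - P12^2
    m0 <- (P22 * r1 - P12 * r2) / det
    m1 <- (P11 * r2 - P12 * r1) / det
    V11 <- P22 / det; V12 <- -P12 / det; V22 <- P11 / det
    L11 <- sqrt(V11); L21 <- V12 / L11; L22 <- sqrt(pmax(V22 - L21^2, 0))
    e1 <- stats::rnorm(J); e2 <- stats::rnorm(J)
    beta0 <- m0 + L11 * e1
    beta1 <- m1 + L21 * e1 + L22 * e2

    # --- log sigma_j: random-walk Metropolis, lake-parallel ---
    if (!sigma_fixed) {
      ssr <- pmax(ss$Syy - 2 * beta0 * ss$Sy - 2 * beta1 * ss$Sxy +
                    ss$n * beta0^2 + 2 * beta0 * beta1 * ss$Sx +
                    beta1^2 * ss$Sxx, 0)
      prop <- ls + step_ls * stats::rnorm(J)
      lp_cur <- -ss$n * ls - 0.5 * ssr * exp(-2 * ls) -
        0.5 * ((ls - mls_j) / sls)^2
      lp_prop <- -ss$n * prop - 0.5 * ssr * exp(-2 * prop) -
        0.5 * ((prop - mls_j) / sls)^2
      ok <- log(stats::runif(J)) < (lp_prop - lp_cur)
      ls[ok] <- prop[ok]
      acc_ls <- acc_ls + ok
      if (!adapting) acc_ls_tot <- acc_ls_tot + ok
    }

    # --- population means: conjugate updates ---
    Q <- matrix(c(Q11, Q12, Q12, Q22), 2, 2)
    if (covariate) {
      B <- rbind(beta0, beta1)          # 2 x J
      Qb <- Q %*% B                     # 2 x J
      rhs4 <- c(rowSums(Qb), as.numeric(Qb %*% z))  # (g00,g10 | g01,g11) order
      A4 <- kronecker(ZtZ, Q) + diag(4) / V0
      gvec <- {
        U <- chol(A4)
        m <- backsolve(U, backsolve(U, rhs4, transpose = TRUE))
        m + backsolve(U, stats::rnorm(4))
      }
      gam <- c(gvec[1], gvec[3], gvec[2], gvec[4])  # -> (g00, g01, g10, g11)
      pm0 <- gam[1] + gam[2] * z
      pm1 <- gam[3] + gam[4] * z
    } else if (!mu_fixed) {
      A2 <- J * Q + diag(2) / V0
      rhs <- Q %*% c(sum(beta0), sum(beta1))
      mu <- .draw_mvn2(A2, rhs)
      pm0 <- rep(mu[1], J); pm1 <- rep(mu[2], J)
    }

    # --- mean of log sigma (or its regression on z): conjugate ---
    if (!sigma_fixed) {
      if (covariate) {
        A2 <- ZtZ / sls^2 + diag(2) / V0
        rhs <- c(sum(ls), sum(z * ls)) / sls^2
        hvec <- .draw_mvn2(A2, rhs)
        mls_j <- hvec[1] + hvec[2] * z
      } else if (!mls_fixed) {
        prec <- J / sls^2 + 1 / V0
        mls <- stats::rnorm(1, (sum(ls) / sls^2) / prec, sqrt(1 / prec))
        mls_j <- rep(mls, J)
      }
    }

    # --- scale parameters: reflected random-walk Metropolis ---
    e0 <- beta0 - pm0; e1d <- beta1 - pm1
    S00 <- sum(e0^2); S01 <- sum(e0 * e1d); S11 <- sum(e1d^2)
    ll_cur <- .ll_bvn(sd0, sd1, rho, S00, S01, S11, J)
    if (!sd0_fixed) {
      p <- .reflect(sd0 + step_sd0 * stats::rnorm(1), 0, sd_hi)
      ll_p <- .ll_bvn(p, sd1, rho, S00, S01, S11, J)
      if (log(stats::runif(1)) < ll_p - ll_cur) {
        sd0 <- p; ll_cur <- ll_p; acc_sd0 <- acc_sd0 + 1
        if (!adapting) acc_sc_tot["sd0"] <- acc_sc_tot["sd0"] + 1
      }
    }
    if (!sd1_fixed) {
      p <- .reflect(sd1 + step_sd1 * stats::rnorm(1), 0, sd_hi)
      ll_p <- .ll_bvn(sd0, p, rho, S00, S01, S11, J)
      if (log(stats::runif(1)) < ll_p - ll_cur) {
        sd1 <- p; ll_cur <- ll_p; acc_sd1 <- acc_sd1 + 1
        if (!adapting) acc_sc_tot["sd1"] <- acc_sc_tot["sd1"] + 1
      }
    }
    if (!rho_fixed) {
      p <- .reflect(rho + step_rho * stats::rnorm(1), -1, 1)
      ll_p <- .ll_bvn(sd0, sd1, p, S00, S01, S11, J)
      if (log(stats::runif(1)) < ll_p - ll_cur) {
        rho <- p; ll_cur <- ll_p; acc_rho <- acc_rho + 1
        if (!adapting) acc_sc_tot["rho"] <- acc_sc_tot["rho"] + 1
      }
    }
    if (!sigma_fixed && !sls_fixed) {
      Sls2 <- sum((ls - mls_j)^2)
      lsd <- function(s) if (s <= 0) -Inf else -J * log(s) - Sls2 / (2 * s^2)
      p <- .reflect(sls + step_sls * stats::rnorm(1), 0, sd_hi)
      if (log(stats::runif(1)) < lsd(p) - lsd(sls)) {
        sls <- p; acc_sls <- acc_sls + 1
        if (!adapting) acc_sc_tot["sls"] <- acc_sc_tot["sls"] + 1
      }
    }

    # --- proposal-scale adaptation (burn-in only) ---
    if (adapting && it %% adapt_every == 0L) {
      tune <- function(step, acc) {
        rate <- acc / adapt_every
        pmin(pmax(step * exp(rate - 0.44), step * 0.5), step * 2)
      }
      step_ls <- tune(step_ls, acc_ls)
      step_sd0 <- tune(step_sd0, acc_sd0)
      step_sd1 <- tune(step_sd1, acc_sd1)
      step_rho <- tune(step_rho, acc_rho)
      step_sls <- tune(step_sls, acc_sls)
      acc_ls[] <- 0; acc_sd0 <- 0; acc_sd1 <- 0; acc_rho <- 0; acc_sls <- 0
    }

    # --- retain ---
    if (it > burn && (it - burn) %% thin == 0L) {
      keep_i <- keep_i + 1L
      if (keep_i <= n_keep) {
        pop <- if (covariate)
          c(gam, sd0, sd1, rho, hvec, sls)
        else
          c(mu, sd0, sd1, rho, mls, sls)
        out[keep_i, ] <- c(pop, beta0, beta1, exp(ls))
      }
    }
  }

  post_iters <- max(n_iter - burn, 1L)
  list(draws = out[seq_len(keep_i), , drop = FALSE],
       acceptance = list(
         logsigma = if (sigma_fixed) NA_real_ else mean(acc_ls_tot) / post_iters,
         sd_beta0 = if (sd0_fixed) NA_real_ else acc_sc_tot[["sd0"]] / post_iters,
         sd_beta1 = if (sd1_fixed) NA_real_ else acc_sc_tot[["sd1"]] / post_iters,
         rho = if (rho_fixed) NA_real_ else acc_sc_tot[["rho"]] / post_iters,
         sd_logsigma = if (sigma_fixed || sls_fixed) NA_real_ else
           acc_sc_tot[["sls"]] / post_iters))
}

.fit_engine <- function(md, priors, settings, model, fixed) {
  stopifnot(inherits(md, "secchi_model_data"),
            inherits(priors, "prior_spec"),
            inherits(settings, "mcmc_settings"))
  ss <- .suff_stats(md)
  n_keep <- ceiling(settings$n_retained_total / settings$n_chains)
  n_iter <- settings$burn_in + n_keep * settings$thin
  set.seed(settings$seed)
  chain_seeds <- sample.int(2147483646L, settings$n_chains)
  t0 <- proc.time()[["elapsed"]]
  chains <- lapply(seq_len(settings$n_chains), function(c) {
    .run_chain(ss, md, priors, model, fixed, n_iter,
               settings$burn_in, settings$thin, n_keep, c, chain_seeds[c])
  })
  structure(list(draws = lapply(chains, `[[`, "draws"),
                 acceptance = lapply(chains, `[[`, "acceptance"),
                 model = model, fixed = fixed,
                 lake_ids = md$lake_ids, center_year = md$center_year,
                 covariate_name = md$covariate_name,
                 settings = settings, priors = priors,
                 runtime_s = proc.time()[["elapsed"]] - t0),
            class = "secchi_fit")
}

#' Fit the unconditional hierarchical trend model
#'
#' Fits, by Metropolis-within-Gibbs MCMC, the varying-intercept,
#' varying-slope, varying-residual-variance model: lake-year log depths are
#' normal around a lake-specific line in the centered year; lake
#' intercept/slope pairs are bivariate normal with population means, SDs and
#' a correlation; lake log residual SDs are normal with their own mean and
#' SD. Conjugate Gibbs updates are used for the lake lines and population
#' means; reflected random-walk Metropolis updates are used for the scale
#' parameters and the lake log residual SDs, with proposal scales adapted
#' during burn-in only.
#'
#' @param md Model data from [build_model_data()].
#' @param priors A [prior_spec()].
#' @param settings An [mcmc_settings()].
#' @param fixed Optional named list pinning parameters at known values
#'   instead of sampling them (for validation against closed-form and
#'   quadrature posteriors): any of `sigma` (scalar or per-lake vector),
#'   `mu_beta` (length 2), `sd_beta0`, `sd_beta1`, `rho`, `mu_logsigma`,
#'   `sd_logsigma`.
#' @return A `secchi_fit` with per-chain draw matrices (columns: population
#'   parameters, then `beta0[lake]`, `beta1[lake]`, `sigma[lake]`), sampler
#'   acceptance rates and metadata.
#' @export
fit_unconditional <- function(md, priors = prior_spec(),
                              settings = mcmc_settings(), fixed = list()) {
  if (md$J < 2 && is.null(fixed$mu_beta))
    stop("need >= 2 lakes to estimate population parameters ",
         "(or fix mu_beta for single-lake validation runs)")
  .fit_engine(md, priors, settings, "unconditional", fixed)
}

#' Fit the covariate (second-stage regression) model
#'
#' As [fit_unconditional()], but the lake-level means are linear in one
#' standardized lake covariate: intercept `g00 + g01 z`, slope
#' `g10 + g11 z`, log residual SD `h0 + h1 z`. Second-stage intercept/slope
#' deviations keep their bivariate correlation, and the log-sigma equation
#' has an independent residual SD. One covariate is fitted at a time.
#'
#' @inheritParams fit_unconditional
#' @export
fit_with_covariate <- function(md, priors = prior_spec(),
                               settings = mcmc_settings(), fixed = list()) {
  if (is.null(md$z))
    stop("model data carries no covariate; pass covariate_name to build_model_data()")
  if (length(unique(md$z)) < 3)
    stop("need >= 3 lakes with distinct covariate values")
  .fit_engine(md, priors, settings, "covariate", fixed)
}

#' Pool retained draws of one parameter across chains
#'
#' @param fit A `secchi_fit`.
#' @param parameter Column name, e.g. `"mu_beta1"` or `"beta1[L0001]"`.
#' @export
pooled_draws <- function(fit, parameter) {
  stopifnot(inherits(fit, "secchi_fit"))
  if (!nzchar(parameter) || !parameter %in% colnames(fit$draws[[1]]))
    stop("unknown parameter: '", parameter, "'")
  unlist(lapply(fit$draws, function(m) m[, parameter]), use.names = FALSE)
}

#' @export
print.secchi_fit <- function(x, ...) {
  cat("Hierarchical Secchi trend fit (", x$model, " model)\n", sep = "")
  cat("  lakes: ", length(x$lake_ids),
      "; chains: ", length(x$draws),
      "; retained draws: ", sum(vapply(x$draws, nrow, 1L)), "\n", sep = "")
  if (!is.null(x$covariate_name))
    cat("  covariate: ", x$covariate_name, "\n", sep = "")
  invisible(x)
}
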