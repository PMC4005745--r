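# Independent oracles and small utilities used across tests. These never call
# the sampler; they compute reference posteriors by closed form or dense grid
# quadrature.

# Monte-Carlo standard error of the mean of a (possibly autocorrelated)
# draw sequence, by non-overlapping batch means.
mcse_mean <- function(x, n_batches = 40) {
  n <- length(x)
  bs <- floor(n / n_batches)
  bm <- colMeans(matrix(x[seq_len(bs * n_batches)], nrow = bs))
  stats::sd(bm) / sqrt(n_batches)
}

# Closed-form posterior of a normal linear regression with known error SD
# and a normal prior N(prior_mean, prior_cov) on the coefficients.
conjugate_blr <- function(X, y, sigma, prior_mean, prior_cov) {
  P <- crossprod(X) / sigma^2 + solve(prior_cov)
  V <- solve(P)
  m <- V %*% (crossprod(X, y) / sigma^2 + solve(prior_cov) %*% prior_mean)
  list(mean = drop(m), sd = sqrt(diag(V)), cov = V)
}

# Dense grid quadrature of the 2-lake hierarchical posterior with the
# residual SD and the among-lake covariance (sd0, sd1, rho) held at known
# values: the lake lines are marginalized analytically (y_j is normal with
# mean X mu and covariance X Sigma X' + sigma^2 I), and the population means
# (mu0, mu1) are integrated on a dense rectangular grid under their
# N(0, V0) prior. Also returns the marginal means of the lake-level
# coefficients via their conditional (linear-in-mu) posterior means.
grid_oracle_two_lakes <- function(ly, sigma, sd0, sd1, rho, center_year,
                                  mu0_range, mu1_range, n_grid = 241,
                                  V0 = 1e6) {
  lakes <- sort(unique(ly$lake_id))
  stopifnot(length(lakes) == 2)
  x <- ly$year[ly$lake_id == lakes[1]] - center_year
  stopifnot(all(ly$year[ly$lake_id == lakes[2]] - center_year == x))
  X <- cbind(1, x)
  Sig <- matrix(c(sd0^2, rho * sd0 * sd1, rho * sd0 * sd1, sd1^2), 2)
  C <- X %*% Sig %*% t(X) + diag(sigma^2, nrow(X))
  Ci <- solve(C)
  ys <- lapply(lakes, function(l) log(ly$mean_secchi_m[ly$lake_id == l]))
  a <- vapply(ys, function(y) drop(t(y) %*% Ci %*% y), 1)
  b <- vapply(ys, function(y) drop(t(X) %*% Ci %*% y), numeric(2))
  M <- t(X) %*% Ci %*% X

  g0 <- seq(mu0_range[1], mu0_range[2], length.out = n_grid)
  g1 <- seq(mu1_range[1], mu1_range[2], length.out = n_grid)
  G <- expand.grid(mu0 = g0, mu1 = g1)
  q <- M[1, 1] * G$mu0^2 + 2 * M[1, 2] * G$mu0 * G$mu1 + M[2, 2] * G$mu1^2
  lp <- -(sum(a) - 2 * ((b[1, 1] + b[1, 2]) * G$mu0 +
                          (b[2, 1] + b[2, 2]) * G$mu1) + 2 * q) / 2 -
    (G$mu0^2 + G$mu1^2) / (2 * V0)
  w <- exp(lp - max(lp)); w <- w / sum(w)
  Emu <- c(sum(w * G$mu0), sum(w * G$mu1))

  P <- crossprod(X) / sigma^2 + solve(Sig)
  Vb <- solve(P)
  K <- Vb %*% solve(Sig)
  Ebeta <- lapply(seq_along(lakes), function(k) {
    drop(Vb %*% (crossprod(X, ys[[k]]) / sigma^2) + K %*% Emu)
  })
  names(Ebeta) <- lakes
  list(mu = Emu, beta = Ebeta)
}

# 1-D grid quadrature over the intercept-slope correlation with everything
# else (residual SD, among-lake SDs, population means) known; lake lines
# marginalized analytically as above. Validates the non-conjugate reflected
# Metropolis update for rho.
grid_oracle_rho <- function(ly, sigma, sd0, sd1, mu, center_year,
                            n_grid = 2001) {
  lakes <- sort(unique(ly$lake_id))
  x <- ly$year[ly$lake_id == lakes[1]] - center_year
  X <- cbind(1, x)
  rr <- seq(-0.999, 0.999, length.out = n_grid)
  lp <- vapply(rr, function(r) {
    Sig <- matrix(c(sd0^2, r * sd0 * sd1, r * sd0 * sd1, sd1^2), 2)
    C <- X %*% Sig %*% t(X) + diag(sigma^2, nrow(X))
    Ci <- solve(C)
    ld <- as.numeric(determinant(C, logarithm = TRUE)$modulus)
    sum(vapply(lakes, function(l) {
      r_ <- log(ly$mean_secchi_m[ly$lake_id == l]) - X %*% mu
      -0.5 * (ld + drop(t(r_) %*% Ci %*% r_))
    }, 1))
  }, 1)
  w <- exp(lp - max(lp)); w <- w / sum(w)
  sum(w * rr)
}

# Minimal stand-in fit object for summary-level tests
fake_fit <- function(chains, lake_ids = character()) {
  structure(list(draws = chains, model = "unconditional",
                 lake_ids = lake_ids, center_year = 0,
                 covariate_name = NULL,
                 settings = mcmc_settings(n_chains = length(chains),
                                          burn_in = 0, thin = 1,
                                          n_retained_total = nrow(chains[[1]]) *
                                            length(chains)),
                 acceptance = list(), priors = prior_spec()),
            class = "secchi_fit")
}
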