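#' Gelman-Rubin potential scale reduction factor
#'
#' Computes the scale reduction factor for one parameter from parallel
#' chains: with `m` chains of `n` draws, `W` the mean within-chain variance
#' and `B` the between-chain variance (`n` times the variance of the chain
#' means), the statistic is `sqrt(((n-1)/n * W + B/n) / W)`. Values near 1
#' indicate the chains have mixed.
#'
#' @param x A `secchi_fit`, or a list of numeric vectors (one per chain).
#' @param parameter Parameter name (required when `x` is a fit).
#' @return The scale reduction factor (a single number).
#' @examples
#' gelman_rubin(list(c(1, 2), c(3, 4)))  # sqrt(4.5)
#' @export
gelman_rubin <- function(x, parameter = NULL) {
  chains <- if (inherits(x, "secchi_fit")) {
    if (is.null(parameter)) stop("parameter name required for a fit object")
    lapply(x$draws, function(m) {
      if (!parameter %in% colnames(m)) stop("unknown parameter: '", parameter, "'")
      m[, parameter]
    })
  } else if (is.list(x)) {
    lapply(x, as.numeric)
  } else stop("x must be a secchi_fit or a list of chains")
  m <- length(chains)
  if (m < 2) stop("need at least 2 chains")
  n <- unique(vapply(chains, length, 1L))
  if (length(n) != 1) stop("chains must have equal length")
  if (n < 2) stop("need at least 2 draws per chain")
  means <- vapply(chains, mean, 1)
  W <- mean(vapply(chains, stats::var, 1))
  if (!is.finite(W) || W == 0) stop("zero within-chain variance")
  B <- n * stats::var(means)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Scale reduction factors for all population-level parameters
#'
#' @param fit A `secchi_fit`.
#' @param lake_level Include lake-level parameters too (default `FALSE`).
#' @return Named numeric vector of scale reduction factors.
#' @export
gelman_rubin_all <- function(fit, lake_level = FALSE) {
  stopifnot(inherits(fit, "secchi_fit"))
  pars <- colnames(fit$draws[[1]])
  if (!lake_level) pars <- pars[!grepl("\\[", pars)]
  vapply(pars, function(p) {
    tryCatch(gelman_rubin(fit, p), error = function(e) NA_real_)
  }, 1)
}
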