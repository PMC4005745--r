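#' Posterior summary of one parameter
#'
#' Pools retained draws across chains and reports the posterior mean and the
#' central 95% credible interval, computed as the empirical 2.5th and 97.5th
#' percentiles with the linear-interpolation quantile rule
#' ([stats::quantile()] type 7).
#'
#' @param fit A `secchi_fit`.
#' @param parameter Parameter name (e.g. `"mu_beta1"`, `"g01"`,
#'   `"beta1[L0001]"`).
#' @return One-row data frame: `parameter`, `mean`, `lower_95`, `upper_95`,
#'   `n_draws`.
#' @export
summarize_parameter <- function(fit, parameter) {
  d <- pooled_draws(fit, parameter)
  q <- unname(stats::quantile(d, c(0.025, 0.975), type = 7, names = FALSE))
  data.frame(parameter = parameter, mean = mean(d),
             lower_95 = q[1], upper_95 = q[2], n_draws = length(d),
             stringsAsFactors = FALSE)
}

#' Convert a log-scale annual slope to percent change per year
#'
#' A slope `b` on the natural-log scale corresponds to a multiplicative
#' change of `exp(b)` per year, i.e. `100 * (exp(b) - 1)` percent per year.
#'
#' @param log_slope Finite numeric slope(s) on the log-e scale (per year).
#' @return Percent change per year.
#' @examples
#' percent_change_per_year(0.0092)  # ~0.92 %/yr
#' @export
percent_change_per_year <- function(log_slope) {
  if (!all(is.finite(log_slope))) stop("log_slope must be finite")
  100 * (exp(log_slope) - 1)
}

#' Posterior probability of an increasing trend for one lake
#'
#' The fraction of pooled retained slope draws that are strictly positive;
#' draws exactly at zero count as not positive.
#'
#' @param fit A `secchi_fit`.
#' @param lake_id Lake identifier.
#' @export
lake_trend_probability <- function(fit, lake_id) {
  stopifnot(inherits(fit, "secchi_fit"))
  if (!lake_id %in% fit$lake_ids) stop("unknown lake: '", lake_id, "'")
  d <- pooled_draws(fit, paste0("beta1[", lake_id, "]"))
  mean(d > 0)
}

#' Trend probabilities for every lake in a fit
#'
#' @param fit A `secchi_fit`.
#' @return Data frame `lake_id`, `p_positive`.
#' @export
lake_trend_probabilities <- function(fit) {
  stopifnot(inherits(fit, "secchi_fit"))
  p <- vapply(fit$lake_ids, function(l)
    mean(pooled_draws(fit, paste0("beta1[", l, "]")) > 0), 1)
  data.frame(lake_id = fit$lake_ids, p_positive = unname(p),
             stringsAsFactors = FALSE)
}

#' Classify lakes by trend probability
#'
#' A lake is classified `increase` if its posterior probability of a positive
#' slope is at least `threshold`, `decline` if the probability of a
#' non-positive slope is at least `threshold`, otherwise `no_trend`.
#' Thresholds are inclusive ("90% or greater").
#'
#' @param probs Data frame with columns `lake_id`, `p_positive` (as from
#'   [lake_trend_probabilities()]), or a named numeric vector.
#' @param threshold Classification threshold in `(0.5, 1]`, default 0.90.
#' @return List with `table` (per-lake categories) and `counts` (lakes and
#'   fraction per category).
#' @export
classify_trends <- function(probs, threshold = 0.90) {
  if (is.numeric(probs))
    probs <- data.frame(lake_id = names(probs) %||% seq_along(probs),
                        p_positive = unname(probs), stringsAsFactors = FALSE)
  if (threshold <= 0.5 || threshold > 1)
    stop("threshold must lie in (0.5, 1]")
  p <- probs$p_positive
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  category <- ifelse(p >= threshold, "increase",
                     ifelse(1 - p >= threshold, "decline", "no_trend"))
  tab <- data.frame(lake_id = probs$lake_id, p_positive = p,
                    category = category, threshold = threshold,
                    stringsAsFactors = FALSE)
  counts <- as.list(table(factor(category,
                                 levels = c("decline", "no_trend", "increase"))))
  counts <- lapply(counts, as.integer)
  counts$n_lakes <- nrow(tab)
  counts$frac_decline <- counts$decline / counts$n_lakes
  counts$frac_increase <- counts$increase / counts$n_lakes
  list(table = tab, counts = counts)
}

#' Is a covariate effect important?
#'
#' Mirrors interval-based assessment: a coefficient is called `important`
#' when its 95% credible interval excludes zero strictly; an interval
#' touching zero at an endpoint counts as overlapping.
#'
#' @param summary One-row data frame from [summarize_parameter()] (or any
#'   data frame with `lower_95`, `upper_95`).
#' @return `"important"` or `"not_important"`.
#' @export
covariate_importance <- function(summary) {
  stopifnot(all(c("lower_95", "upper_95") %in% names(summary)))
  if (summary$lower_95 > 0 || summary$upper_95 < 0) "important" else "not_important"
}

#' Inter-annual coefficient of variation of summer means
#'
#' `100 * sd / mean` of a lake's annual summer mean depths, with the sample
#' (n-1) SD; a lake needs at least two lake-year records.
#'
#' @param ly Lake-year table.
#' @param lake_id Lake identifier.
#' @return CV in percent.
#' @export
interannual_cv <- function(ly, lake_id) {
  m <- ly$mean_secchi_m[ly$lake_id == lake_id]
  if (length(m) < 2) stop("lake '", lake_id, "' has fewer than 2 lake-years")
  mu <- mean(m)
  if (mu == 0) stop("zero mean annual depth")
  100 * stats::sd(m) / mu
}

#' Inter-annual CVs for all lakes with at least two years
#'
#' @param ly Lake-year table.
#' @return Data frame `lake_id`, `cv_percent`, `n_years`.
#' @export
interannual_cv_all <- function(ly) {
  counts <- table(ly$lake_id)
  lakes <- names(counts)[counts >= 2]
  data.frame(lake_id = lakes,
             cv_percent = vapply(lakes, function(l) interannual_cv(ly, l), 1),
             n_years = as.integer(counts[lakes]),
             stringsAsFactors = FALSE, row.names = NULL)
}
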