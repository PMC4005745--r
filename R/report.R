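#' Persist posterior draws as long-format CSV plus a JSON run manifest
#'
#' Writes `draws.csv` (columns `chain`, `iteration`, `parameter`, `value`)
#' and `manifest.json` (model, settings, seed, acceptance rates, scale
#' reduction factors for population-level parameters). Output is bit-stable
#' under rerun with the same seed.
#'
#' @param fit A `secchi_fit`.
#' @param dir Output directory (created if needed).
#' @param lake_level Persist lake-level draws too (default `FALSE`; they can
#'   be large).
#' @export
write_draws <- function(fit, dir, lake_level = FALSE) {
  stopifnot(inherits(fit, "secchi_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pars <- colnames(fit$draws[[1]])
  if (!lake_level) pars <- pars[!grepl("\\[", pars)]
  long <- do.call(rbind, lapply(seq_along(fit$draws), function(c) {
    m <- fit$draws[[c]][, pars, drop = FALSE]
    data.frame(chain = c, iteration = rep(seq_len(nrow(m)), times = length(pars)),
               parameter = rep(pars, each = nrow(m)),
               value = sprintf("%.17g", as.numeric(m)),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(long, file.path(dir, "draws.csv"), row.names = FALSE)
  manifest <- list(model = fit$model,
                   covariate = fit$covariate_name,
                   center_year = fit$center_year,
                   settings = unclass(fit$settings),
                   acceptance = fit$acceptance,
                   scale_reduction = as.list(gelman_rubin_all(fit)),
                   runtime_s = fit$runtime_s)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(dir)
}

#' Assemble the analysis report
#'
#' Collects the headline quantities of a fitted trend analysis: the
#' population trend as percent change per year with its 95% credible
#' interval, per-lake trend classifications and their counts, covariate
#' importance calls for any covariate fits supplied, and the distribution of
#' inter-annual CVs. Returns a list and, optionally, writes deterministic
#' JSON and plain-text renderings.
#'
#' @param ly Lake-year table used for the fit.
#' @param fit Unconditional `secchi_fit`.
#' @param covariate_fits Optional named list of covariate `secchi_fit`s
#'   (names identify the covariate).
#' @param threshold Trend-classification threshold, default 0.90.
#' @param path Optional output stem; writes `<path>.json` and `<path>.txt`.
#' @return The report as a list.
#' @export
render_report <- function(ly, fit, covariate_fits = NULL, threshold = 0.90,
                          path = NULL) {
  stopifnot(inherits(fit, "secchi_fit"))
  if (fit$model != "unconditional")
    stop("fit must be the unconditional model; pass covariate fits separately")
  slope <- summarize_parameter(fit, "mu_beta1")
  trend <- list(
    mean_log_slope = slope$mean,
    percent_per_year = percent_change_per_year(slope$mean),
    percent_per_year_cri = percent_change_per_year(
      c(slope$lower_95, slope$upper_95)),
    n_draws = slope$n_draws)

  cls <- classify_trends(lake_trend_probabilities(fit), threshold)

  cov_section <- NULL
  if (!is.null(covariate_fits) && length(covariate_fits)) {
    rows <- lapply(names(covariate_fits), function(nm) {
      f <- covariate_fits[[nm]]
      do.call(rbind, lapply(c("g01", "g11", "h1"), function(p) {
        s <- summarize_parameter(f, p)
        data.frame(covariate = nm, parameter = p, mean = s$mean,
                   lower_95 = s$lower_95, upper_95 = s$upper_95,
                   importance = covariate_importance(s),
                   stringsAsFactors = FALSE)
      }))
    })
    cov_section <- do.call(rbind, rows)
  }

  cvs <- interannual_cv_all(ly)
  cv_section <- list(
    n_lakes = nrow(cvs),
    frac_below_30 = if (nrow(cvs)) mean(cvs$cv_percent < 30) else NA,
    quartiles = if (nrow(cvs))
      unname(stats::quantile(cvs$cv_percent, c(0.25, 0.5, 0.75))) else NULL,
    range = if (nrow(cvs)) range(cvs$cv_percent) else NULL)

  report <- list(population_trend = trend,
                 trend_classification = cls$counts,
                 covariate_importance = cov_section,
                 interannual_cv = cv_section)

  if (!is.null(path)) {
    jsonlite::write_json(report, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE,
                         dataframe = "rows")
    txt <- c(
      "Secchi depth trend analysis",
      "===========================",
      sprintf("Population trend: %.2f %%/yr (95%% CRI %.2f to %.2f)",
              trend$percent_per_year, trend$percent_per_year_cri[1],
              trend$percent_per_year_cri[2]),
      sprintf("Lakes: %d | increase %d (%.1f%%), decline %d (%.1f%%), no trend %d",
              cls$counts$n_lakes, cls$counts$increase,
              100 * cls$counts$frac_increase, cls$counts$decline,
              100 * cls$counts$frac_decline, cls$counts$no_trend),
      if (!is.null(cov_section)) c(
        "Covariate effects (g01 intercept, g11 slope, h1 log residual SD):",
        sprintf("  %s %s: %.4f [%.4f, %.4f] %s", cov_section$covariate,
                cov_section$parameter, cov_section$mean, cov_section$lower_95,
                cov_section$upper_95, cov_section$importance))
      else "Covariate section: absent (no covariate fits supplied)",
      sprintf("Inter-annual CV: %.0f%% of %d lakes below 30%%",
              100 * cv_section$frac_below_30, cv_section$n_lakes))
    writeLines(txt, paste0(path, ".txt"))
  }
  report
}
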