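# Plain-CSV readers/writers for the pipeline's table interfaces. Column
# sets match the documented formats; readers validate, writers round-trip.

.read_checked <- function(path, need) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(need, names(d))
  if (length(missing) > 0L) {
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing, collapse = ", ")))
  }
  d
}

#' Read pipeline input tables
#'
#' `read_climate()` expects `plot_id, date, tmean_c, precip_mm`;
#' `read_terrain()` `plot_id, slope_deg, aspect_deg, sdr_m, awc_frac,
#' cfv_frac`; `read_trees()` `plot_id, census_id, census_date, tree_id,
#' species, dbh_cm`; `read_plots()` `plot_id, plot_area_ha`;
#' `read_traits()` `species, genus, shade_tol, drought_tol, sca`.
#'
#' @param path CSV file path.
#' @return Data frame with validated columns.
#' @export
read_climate <- function(path) {
  .read_checked(path, c("plot_id", "date", "tmean_c", "precip_mm"))
}

#' @rdname read_climate
#' @export
read_terrain <- function(path) {
  .read_checked(path, c("plot_id", "slope_deg", "aspect_deg", "sdr_m",
                        "awc_frac", "cfv_frac"))
}

#' @rdname read_climate
#' @export
read_trees <- function(path) {
  .read_checked(path, c("plot_id", "census_id", "census_date", "tree_id",
                        "species", "dbh_cm"))
}

#' @rdname read_climate
#' @export
read_plots <- function(path) {
  .read_checked(path, c("plot_id", "plot_area_ha"))
}

#' @rdname read_climate
#' @export
read_traits <- function(path) {
  .read_checked(path, c("species", "genus", "shade_tol", "drought_tol", "sca"))
}

#' Write a pipeline output table
#'
#' Thin wrapper over `write.csv` without row names, used for
#' `site_env.csv`, `observations.csv`, `stand.csv`, `groups.csv`,
#' `effects.csv`, `curves.csv` and the posterior draws table.
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Write posterior draws as a long CSV
#'
#' One row per chain x iteration, one column per parameter.
#'
#' @param fit A `recruitment_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_draws <- function(fit, path) {
  d <- do.call(rbind, lapply(seq_along(fit$draws), function(ch) {
    data.frame(chain = ch, iteration = seq_len(nrow(fit$draws[[ch]])),
               fit$draws[[ch]], check.names = FALSE)
  }))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Write convergence and residual diagnostics as JSON
#'
#' @param fit A `recruitment_fit`.
#' @param path Output path (JSON).
#' @param n_sim Simulations per observation for the residual summary.
#' @return `path`, invisibly.
#' @export
write_diagnostics <- function(fit, path, n_sim = 100) {
  conv <- convergence(fit)
  res <- scaled_residuals(fit, n_sim = n_sim)
  ks <- suppressWarnings(stats::ks.test(res$residuals, "punif"))
  out <- list(
    max_rhat = attr(conv, "max_rhat"),
    min_ess = min(conv$ess, na.rm = TRUE),
    rhat = stats::setNames(conv$rhat, conv$parameter),
    ess = stats::setNames(conv$ess, conv$parameter),
    residual_ks_stat = unname(ks$statistic),
    residual_ks_p = ks$p.value,
    zero_calibration = as.list(res$zero_calibration)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
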