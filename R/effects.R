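# Posterior presentation layer: mean-over-groups + deviation effect
# estimates, per-variable effect curves, and basal-area x stem-density
# interaction surfaces.

# columns of the draw matrix holding beta[g, var] for all groups
.beta_cols <- function(fit, variable) {
  paste0("beta[", levels(fit$design$group), ",", variable, "]")
}

#' Effect estimates: mean over trait groups and group deviations
#'
#' For every covariate and every posterior draw, computes the mean of the
#' trait-group coefficients over groups and each group's deviation from
#' that mean; both are summarized by their posterior mean and 95% credible
#' interval.
#'
#' @param fit A `recruitment_fit`.
#' @param prob Credible-interval mass (default 0.95).
#' @return Data frame `variable, group, overall_mean, overall_lo,
#'   overall_hi, deviation, dev_lo, dev_hi` (the overall columns repeat
#'   within a variable).
#' @export
effect_estimates <- function(fit, prob = 0.95) {
  draws <- as_draws_matrix(fit)
  qs <- c((1 - prob) / 2, 1 - (1 - prob) / 2)
  groups <- levels(fit$design$group)
  out <- lapply(fit$design$vars, function(v) {
    B <- draws[, .beta_cols(fit, v), drop = FALSE]  # draws x groups
    overall <- rowMeans(B)
    dev <- B - overall
    oq <- stats::quantile(overall, qs)
    data.frame(
      variable = v, group = groups,
      overall_mean = mean(overall), overall_lo = oq[1], overall_hi = oq[2],
      deviation = colMeans(dev),
      dev_lo = apply(dev, 2, stats::quantile, qs[1]),
      dev_hi = apply(dev, 2, stats::quantile, qs[2]),
      row.names = NULL, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

# group-restricted percentile grid of a raw covariate
.group_grid <- function(design, variable, group, probs, n = NULL) {
  sel <- design$group == group
  if (!any(sel)) stop(sprintf("group '%s' absent from the data", group))
  x <- design$raw[sel, variable]
  rng <- stats::quantile(x, probs)
  if (is.null(n)) rng else seq(rng[1], rng[2], length.out = n)
}

#' Posterior effect curve for one covariate and trait group
#'
#' Sweeps the focal covariate over the group's 1st to 99th percentile of
#' observed values with every other standardized covariate at its mean
#' (zero), random effects at zero, and the exposure fixed (default 1 ha
#' over 1 year), so that predictions are recruits per ha per year. Each
#' retained draw contributes `mu = exp(beta0_g + beta_g^(focal) x)`; the
#' posterior mean and credible band are returned per grid point.
#'
#' @param fit A `recruitment_fit`.
#' @param variable One of the design's main-effect names.
#' @param group A trait-group label present in the data.
#' @param grid_n Number of grid points (default 50).
#' @param exposure Offset on the natural scale, `area_ha * years`
#'   (default 1).
#' @param prob Credible mass (default 0.95).
#' @return Data frame `variable, group, value` (raw covariate scale),
#'   `mean, lo, hi` (recruits per ha per year).
#' @export
effect_curve <- function(fit, variable, group, grid_n = 50, exposure = 1,
                         prob = 0.95) {
  design <- fit$design
  if (!variable %in% design$mains) {
    stop(sprintf("'%s' is not a main-effect variable", variable))
  }
  grid <- .group_grid(design, variable, group, c(0.01, 0.99), grid_n)
  xz <- (grid - design$center[variable]) / design$scale[variable]
  draws <- as_draws_matrix(fit)
  b0 <- draws[, paste0("beta0[", group, "]")]
  bv <- draws[, paste0("beta[", group, ",", variable, "]")]
  qs <- c((1 - prob) / 2, 1 - (1 - prob) / 2)
  mu <- exposure * exp(outer(b0, rep(1, grid_n)) + outer(bv, xz))
  data.frame(
    variable = variable, group = group, value = grid,
    mean = colMeans(mu),
    lo = apply(mu, 2, stats::quantile, qs[1]),
    hi = apply(mu, 2, stats::quantile, qs[2]),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Basal-area x stem-density interaction surface
#'
#' Predicted recruitment against basal area (1st-99th percentile of the
#' group's observations) at the 10th, 30th, 50th, 70th and 90th percentile
#' of stem density, including the interaction coefficient; all other
#' covariates at their mean, random effects zero, exposure fixed.
#'
#' @inheritParams effect_curve
#' @param density_probs Stem-density percentiles (default
#'   `c(.1, .3, .5, .7, .9)`).
#' @return Data frame `group, density_percentile, stem_density,
#'   basal_area, mean, lo, hi`.
#' @export
interaction_surface <- function(fit, group, grid_n = 50,
                                density_probs = c(0.1, 0.3, 0.5, 0.7, 0.9),
                                exposure = 1, prob = 0.95) {
  design <- fit$design
  need <- c("basal_area", "stem_density")
  if (!all(need %in% design$mains)) {
    stop("design lacks basal_area/stem_density")
  }
  ba <- .group_grid(design, "basal_area", group, c(0.01, 0.99), grid_n)
  dens <- .group_grid(design, "stem_density", group, density_probs)
  ba_z <- (ba - design$center["basal_area"]) / design$scale["basal_area"]
  dens_z <- (dens - design$center["stem_density"]) / design$scale["stem_density"]
  draws <- as_draws_matrix(fit)
  b0 <- draws[, paste0("beta0[", group, "]")]
  b_ba <- draws[, paste0("beta[", group, ",basal_area]")]
  b_de <- draws[, paste0("beta[", group, ",stem_density]")]
  b_int <- if ("ba_x_density" %in% design$vars) {
    draws[, paste0("beta[", group, ",ba_x_density]")]
  } else {
    rep(0, nrow(draws))
  }
  qs <- c((1 - prob) / 2, 1 - (1 - prob) / 2)
  out <- lapply(seq_along(dens), function(k) {
    eta <- outer(b0 + b_de * dens_z[k], rep(1, grid_n)) +
      outer(b_ba + b_int * dens_z[k], ba_z)
    mu <- exposure * exp(eta)
    data.frame(
      group = group, density_percentile = 100 * density_probs[k],
      stem_density = dens[k], basal_area = ba,
      mean = colMeans(mu),
      lo = apply(mu, 2, stats::quantile, qs[1]),
      hi = apply(mu, 2, stats::quantile, qs[2]),
      row.names = NULL, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
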