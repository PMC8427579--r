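#' Default priors for the recruitment model
#'
#' Weakly informative and proper: normal(0, `beta_sd`) on the trait-group
#' intercepts and coefficients, half-normal(0, `sigma_sd`) on every
#' random-effect scale, gamma(`phi_shape`, rate `phi_rate`) on the NB
#' dispersion.
#'
#' @param beta_sd,sigma_sd,phi_shape,phi_rate Prior hyperparameters.
#' @return Named list of hyperparameters.
#' @export
default_priors <- function(beta_sd = 5, sigma_sd = 2,
                           phi_shape = 2, phi_rate = 0.1) {
  list(beta_sd = beta_sd, sigma_sd = sigma_sd,
       phi_shape = phi_shape, phi_rate = phi_rate)
}

#' Initialize a model parameter set for a design
#'
#' All coefficients and random effects zero, unit scales; used as the
#' reference structure everywhere parameters are flattened or restored.
#'
#' @param design A [build_design()] object.
#' @return List with `beta0` (per group), `beta` (group x variable),
#'   `u0_plot`, `u0_species`, `u_species` (species x variable),
#'   `sigma_plot`, `sigma_species`, `sigma_slope` (per variable), `phi`.
#' @export
init_params <- function(design) {
  G <- levels(design$group); J <- levels(design$species); I <- levels(design$plot)
  M <- design$vars
  list(
    beta0 = stats::setNames(numeric(length(G)), G),
    beta = matrix(0, length(G), length(M), dimnames = list(G, M)),
    u0_plot = stats::setNames(numeric(length(I)), I),
    u0_species = stats::setNames(numeric(length(J)), J),
    u_species = matrix(0, length(J), length(M), dimnames = list(J, M)),
    sigma_plot = 1, sigma_species = 1,
    sigma_slope = stats::setNames(rep(1, length(M)), M),
    phi = 1
  )
}

#' Linear predictor of the recruitment model
#'
#' `eta = offset + beta0_g + u0_i + u0_j + sum_m (beta_g^(m) + u_j^(m)) x^(m)`.
#'
#' @param params Parameter list (see [init_params()]).
#' @param design A [build_design()] object.
#' @return Numeric vector, one value per observation row.
#' @export
linear_predictor <- function(params, design) {
  gi <- as.integer(design$group)
  ii <- as.integer(design$plot)
  ji <- as.integer(design$species)
  coefs <- params$beta[gi, , drop = FALSE] + params$u_species[ji, , drop = FALSE]
  unname(design$offset + params$beta0[gi] + params$u0_plot[ii] +
           params$u0_species[ji] + rowSums(coefs * design$X))
}

# Half-normal log-density (x >= 0).
.lhalfnorm <- function(x, sd) {
  ifelse(x < 0, -Inf, log(2) + stats::dnorm(x, 0, sd, log = TRUE))
}

#' Log joint posterior density (up to a constant)
#'
#' NB likelihood with the Eq.-style linear predictor, normal densities of
#' the plot/species random intercepts and species random slopes, and the
#' [default_priors()] densities. Returns `-Inf` for non-finite means or
#' out-of-support parameters.
#'
#' @inheritParams linear_predictor
#' @param priors See [default_priors()].
#' @param family Count family name (default `"nb"`); non-NB families take
#'   their shape parameters from `params$shape` (named list).
#' @return Scalar log density.
#' @export
log_posterior <- function(params, design, priors = default_priors(),
                          family = "nb") {
  if (params$sigma_plot <= 0 || params$sigma_species <= 0 ||
      any(params$sigma_slope <= 0)) {
    return(-Inf)
  }
  eta <- linear_predictor(params, design)
  mu <- exp(eta)
  if (any(!is.finite(mu)) || any(mu <= 0)) return(-Inf)
  ll <- if (family == "nb") {
    if (params$phi <= 0) return(-Inf)
    sum(nb_log_pmf(design$y, mu, params$phi))
  } else {
    fam <- .count_family(family)
    sum(fam$logpmf(design$y, mu, params$shape))
  }
  lre <- sum(stats::dnorm(params$u0_plot, 0, params$sigma_plot, log = TRUE)) +
    sum(stats::dnorm(params$u0_species, 0, params$sigma_species, log = TRUE)) +
    sum(stats::dnorm(params$u_species, 0,
                     rep(params$sigma_slope, each = nrow(params$u_species)),
                     log = TRUE))
  lprior <- sum(stats::dnorm(params$beta0, 0, priors$beta_sd, log = TRUE)) +
    sum(stats::dnorm(params$beta, 0, priors$beta_sd, log = TRUE)) +
    .lhalfnorm(params$sigma_plot, priors$sigma_sd) +
    .lhalfnorm(params$sigma_species, priors$sigma_sd) +
    sum(.lhalfnorm(params$sigma_slope, priors$sigma_sd))
  if (family == "nb") {
    lprior <- lprior + stats::dgamma(params$phi, shape = priors$phi_shape,
                                     rate = priors$phi_rate, log = TRUE)
  }
  ll + lre + lprior
}
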