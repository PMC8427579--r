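#' Fast MAP (and Laplace) fit of the fixed-effect recruitment model
#'
#' Maximizes the log posterior of the fixed-effect part of the model
#' (trait-group intercepts, group-specific or pooled covariate
#' coefficients, and the family shape parameters on their unconstrained
#' scales) with random effects fixed at zero. Optionally draws from the
#' Laplace (normal) approximation around the mode. Used as the fast mode
#' for family screening and small toy models; the full hierarchical model
#' is fit with [fit_posterior()].
#'
#' @param design A [build_design()] object.
#' @param family Count family name (see [count_families()]).
#' @param group_slopes If `TRUE` (default) each trait group gets its own
#'   coefficient per covariate; if `FALSE` slopes are pooled across groups.
#' @param priors See [default_priors()]; `beta_sd` is applied to all
#'   coefficients, the gamma prior to `phi` (with log-scale Jacobian) and a
#'   normal(0, 2.5) prior to `logit_pi`.
#' @param laplace_draws Number of draws from the Laplace approximation
#'   (0 for none).
#' @param seed Seed for the Laplace draws.
#' @return List with `par` (named MAP vector), `value` (log posterior at
#'   the mode), `eta` (linear predictor at the mode), `shape` (family shape
#'   parameters at the mode), `beta0`, `beta`, `convergence`, and `draws`
#'   (Laplace draws matrix, if requested).
#' @export
fit_map <- function(design, family = "nb", group_slopes = TRUE,
                    priors = default_priors(), laplace_draws = 0, seed = 1) {
  stopifnot(inherits(design, "recruitment_design"))
  fam <- .count_family(family)
  y <- design$y
  gi <- as.integer(design$group)
  G <- nlevels(design$group)
  M <- ncol(design$X)

  # fixed-effect model matrix: group dummies, then coefficients
  D <- matrix(0, length(y), G)
  D[cbind(seq_along(y), gi)] <- 1
  if (M > 0L) {
    Xc <- if (group_slopes) {
      do.call(cbind, lapply(seq_len(M), function(m) D * design$X[, m]))
    } else {
      design$X
    }
    Xf <- cbind(D, Xc)
  } else {
    Xf <- D
  }
  cn <- paste0("beta0[", levels(design$group), "]")
  if (M > 0L) {
    cn <- c(cn, if (group_slopes) {
      paste0("beta[", rep(levels(design$group), M), ",",
             rep(colnames(design$X), each = G), "]")
    } else {
      paste0("beta[", colnames(design$X), "]")
    })
  }
  colnames(Xf) <- cn
  p_fix <- ncol(Xf)
  shape_names <- fam$shape
  par0 <- c(stats::setNames(rep(0, p_fix), cn),
            stats::setNames(rep(0, length(shape_names)), shape_names))
  par0[cn[1:G]] <- log(max(mean(y), 0.01) / mean(exp(design$offset)))

  shape_prior <- function(shape) {
    lp <- 0
    if ("log_phi" %in% names(shape)) {
      phi <- exp(shape$log_phi)
      lp <- lp + stats::dgamma(phi, priors$phi_shape, rate = priors$phi_rate,
                               log = TRUE) + shape$log_phi
    }
    if ("logit_pi" %in% names(shape)) {
      lp <- lp + stats::dnorm(shape$logit_pi, 0, 2.5, log = TRUE)
    }
    lp
  }

  obj <- function(par) {
    b <- par[seq_len(p_fix)]
    shape <- as.list(par[-seq_len(p_fix)])
    eta <- design$offset + drop(Xf %*% b)
    mu <- exp(eta)
    if (any(!is.finite(mu))) return(1e10)
    ll <- sum(fam$logpmf(y, mu, shape))
    if (!is.finite(ll)) return(1e10)
    -(ll + sum(stats::dnorm(b, 0, priors$beta_sd, log = TRUE)) +
        shape_prior(shape))
  }
  # analytic gradient for the closed-form families
  grad <- if (family %in% c("poisson", "nb")) {
    function(par) {
      b <- par[seq_len(p_fix)]
      shape <- as.list(par[-seq_len(p_fix)])
      eta <- design$offset + drop(Xf %*% b)
      mu <- exp(eta)
      if (family == "poisson") {
        deta <- y - mu
        gsh <- numeric(0)
      } else {
        phi <- exp(shape$log_phi)
        deta <- y - (y + phi) * mu / (mu + phi)
        dphi <- sum(digamma(y + phi) - digamma(phi) +
                      log(phi / (mu + phi)) + (mu - y) / (mu + phi))
        gsh <- dphi * phi +
          (priors$phi_shape - 1) - priors$phi_rate * phi + 1  # prior + Jacobian
      }
      -c(drop(crossprod(Xf, deta)) - b / priors$beta_sd^2, gsh)
    }
  } else {
    NULL
  }

  opt <- stats::optim(par0, obj, gr = grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  par <- opt$par
  b <- par[seq_len(p_fix)]
  shape <- as.list(par[-seq_len(p_fix)])
  out <- list(
    par = par, value = -opt$value,
    eta = design$offset + drop(Xf %*% b),
    shape = shape,
    beta0 = b[1:G],
    beta = if (M > 0L) par[(G + 1):p_fix] else numeric(0),
    family = family, group_slopes = group_slopes,
    convergence = opt$convergence
  )
  if (laplace_draws > 0) {
    set.seed(seed)
    H <- stats::optimHess(par, obj, gr = grad)
    cov <- tryCatch(solve(H), error = function(e) NULL)
    if (is.null(cov)) {
      warning("singular Hessian; Laplace draws unavailable")
    } else {
      # symmetrize and draw
      cov <- (cov + t(cov)) / 2
      ev <- eigen(cov, symmetric = TRUE)
      ev$values <- pmax(ev$values, 1e-12)
      L <- ev$vectors %*% diag(sqrt(ev$values), length(ev$values))
      z <- matrix(stats::rnorm(laplace_draws * length(par)), length(par))
      out$draws <- t(par + L %*% z)
      colnames(out$draws) <- names(par)
    }
  }
  out
}
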