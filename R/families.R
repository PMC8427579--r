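#' Negative-binomial log probability mass (NB2)
#'
#' Mean/dispersion parameterization with variance `mu + mu^2/phi`;
#' `P(0) = (phi/(mu + phi))^phi`. Converges to the Poisson as
#' `phi -> Inf`.
#'
#' @param y Non-negative integer counts.
#' @param mu Mean, `> 0` (recycled).
#' @param phi Dispersion, `> 0`.
#' @return Log probabilities.
#' @examples
#' nb_log_pmf(0, 2, 1)  # log(1/3)
#' @export
nb_log_pmf <- function(y, mu, phi) {
  if (any(y < 0) || any(y != floor(y))) stop("`y` must be non-negative integers")
  if (any(mu <= 0) || any(phi <= 0)) stop("`mu` and `phi` must be > 0")
  lgamma(y + phi) - lgamma(phi) - lgamma(y + 1) +
    phi * (log(phi) - log(mu + phi)) + y * (log(mu) - log(mu + phi))
}

# Internal count-family registry. Each family exposes
#   logpmf(y, mu, shape)  -- shape: named list of family parameters
#   simulate(n, mu, shape)
#   shape_init / shape names (unconstrained parameterization used by MAP)
# mu is always the exp(offset + linear predictor) mean of the count process.
.count_family <- function(name) {
  switch(name,
    poisson = list(
      name = "poisson", shape = character(0),
      logpmf = function(y, mu, shape) stats::dpois(y, mu, log = TRUE),
      simulate = function(n, mu, shape) stats::rpois(n, mu)
    ),
    nb = list(
      name = "nb", shape = "log_phi",
      logpmf = function(y, mu, shape) nb_log_pmf(y, mu, exp(shape$log_phi)),
      simulate = function(n, mu, shape) {
        stats::rnbinom(n, size = exp(shape$log_phi), mu = mu)
      }
    ),
    `zi-poisson` = list(
      name = "zi-poisson", shape = "logit_pi",
      logpmf = function(y, mu, shape) {
        p <- stats::plogis(shape$logit_pi)
        ll <- log1p(-p) + stats::dpois(y, mu, log = TRUE)
        is0 <- y == 0
        ll[is0] <- log(p + exp(log1p(-p) - mu[is0]))
        ll
      },
      simulate = function(n, mu, shape) {
        p <- stats::plogis(shape$logit_pi)
        ifelse(stats::runif(n) < p, 0L, stats::rpois(n, mu))
      }
    ),
    `zi-nb` = list(
      name = "zi-nb", shape = c("log_phi", "logit_pi"),
      logpmf = function(y, mu, shape) {
        p <- stats::plogis(shape$logit_pi)
        phi <- exp(shape$log_phi)
        ll <- log1p(-p) + nb_log_pmf(y, mu, phi)
        is0 <- y == 0
        lp0 <- phi * (log(phi) - log(mu[is0] + phi))
        ll[is0] <- log(p + exp(log1p(-p) + lp0))
        ll
      },
      simulate = function(n, mu, shape) {
        p <- stats::plogis(shape$logit_pi)
        phi <- exp(shape$log_phi)
        ifelse(stats::runif(n) < p, 0L, stats::rnbinom(n, size = phi, mu = mu))
      }
    ),
    `hurdle-nb` = list(
      name = "hurdle-nb", shape = c("log_phi", "logit_pi"),
      logpmf = function(y, mu, shape) {
        # pi is the probability of a (structural) zero; positive counts
        # follow a zero-truncated NB
        p <- stats::plogis(shape$logit_pi)
        phi <- exp(shape$log_phi)
        lp0 <- phi * (log(phi) - log(mu + phi))
        ll <- log1p(-p) + nb_log_pmf(y, mu, phi) - log1p(-exp(lp0))
        ll[y == 0] <- log(p)
        ll
      },
      simulate = function(n, mu, shape) {
        p <- stats::plogis(shape$logit_pi)
        phi <- exp(shape$log_phi)
        out <- integer(n)
        pos <- stats::runif(n) >= p
        # inverse-cdf sampling of the zero-truncated NB via a uniform on
        # (P(0), 1)
        if (any(pos)) {
          u <- stats::runif(sum(pos))
          p0 <- (phi / (mu[pos] + phi))^phi
          out[pos] <- stats::qnbinom(p0 + u * (1 - p0), size = phi, mu = mu[pos])
          out[pos] <- pmax(out[pos], 1L)
        }
        out
      }
    ),
    stop(sprintf("unknown count family '%s'", name))
  )
}

#' Available count families
#'
#' @return Character vector of family names usable in [fit_map()] and
#'   [compare_families()].
#' @export
count_families <- function() {
  c("poisson", "nb", "zi-poisson", "zi-nb", "hurdle-nb")
}
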