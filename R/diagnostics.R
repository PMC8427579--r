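# Convergence diagnostics: rank-normalized split-chain Gelman-Rubin
# statistic and effective sample size, computed from first principles.

# split each chain's draws in half (dropping one draw if odd)
.split_chain_matrix <- function(col_by_chain) {
  m <- nrow(col_by_chain)
  h <- m %/% 2L
  cbind(col_by_chain[seq_len(h), , drop = FALSE],
        col_by_chain[(m - h + 1L):m, , drop = FALSE])
}

# rank-normalization (fractional offset 3/8) applied over all draws pooled
.rank_normalize <- function(x) {
  r <- rank(x, ties.method = "average")
  stats::qnorm((r - 3 / 8) / (length(x) + 1 / 4))
}

# basic split-Rhat on an iterations x chains matrix (already transformed)
.rhat_basic <- function(z) {
  m <- nrow(z)
  w <- mean(apply(z, 2, stats::var))
  b <- m * stats::var(colMeans(z))
  if (w == 0) return(NA_real_)
  sqrt(((m - 1) / m * w + b / m) / w)
}

# Geyer initial-monotone-sequence ESS on an iterations x chains matrix
.ess_basic <- function(z) {
  m <- nrow(z); c <- ncol(z)
  if (m < 4L) return(NA_real_)
  w <- mean(apply(z, 2, stats::var))
  b <- m * stats::var(colMeans(z))
  var_plus <- (m - 1) / m * w + b / m
  if (var_plus == 0) return(NA_real_)
  lag_max <- min(m - 1L, 1000L)
  acov <- vapply(seq_len(c), function(k) {
    stats::acf(z[, k], lag.max = lag_max, type = "covariance",
               plot = FALSE, demean = TRUE)$acf[, 1, 1]
  }, numeric(lag_max + 1L))
  rho <- 1 - (w - rowMeans(acov)) / var_plus  # rho[1] is lag 0 (=~1)
  # paired sums, truncated at the first negative pair, forced monotone
  tau <- 1
  prev <- Inf
  t <- 2L
  while (t + 1L <= length(rho)) {
    p <- rho[t] + rho[t + 1L]
    if (p < 0) break
    p <- min(p, prev)
    tau <- tau + 2 * p
    prev <- p
    t <- t + 2L
  }
  min(c * m / tau, c * m)
}

#' Convergence diagnostics for a recruitment fit
#'
#' Computes the rank-normalized split-chain Gelman-Rubin diagnostic (R-hat)
#' and a rank-normalized effective sample size for every sampled parameter.
#' Values of R-hat below 1.01 indicate that the chains cover the same
#' stationary distribution.
#'
#' @param fit A `recruitment_fit` with at least two chains, or a list of
#'   equally sized draw matrices.
#' @return A data frame `parameter, rhat, ess`, with attribute `max_rhat`.
#' @export
convergence <- function(fit) {
  draws <- if (inherits(fit, "recruitment_fit")) fit$draws else fit
  if (length(draws) < 2L) stop("convergence diagnostics need >= 2 chains")
  if (length(unique(vapply(draws, nrow, 1L))) != 1L) {
    stop("chains must have equal numbers of draws")
  }
  pn <- colnames(draws[[1]])
  out <- data.frame(parameter = pn, rhat = NA_real_, ess = NA_real_,
                    stringsAsFactors = FALSE)
  for (p in seq_along(pn)) {
    z <- .split_chain_matrix(vapply(draws, function(d) d[, p], draws[[1]][, p]))
    zr <- matrix(.rank_normalize(as.vector(z)), nrow(z), ncol(z))
    out$rhat[p] <- .rhat_basic(zr)
    out$ess[p] <- .ess_basic(zr)
  }
  attr(out, "max_rhat") <- max(out$rhat, na.rm = TRUE)
  out
}

#' Randomized quantile (scaled) residuals
#'
#' For each observation, simulates `n_sim` posterior-predictive counts
#' (parameter draws sampled from the posterior, fitted random effects
#' included) and returns the randomized rank of the observed count among
#' the simulations. Under a correctly specified model the residuals are
#' uniform on `[0, 1]`.
#'
#' @param fit A `recruitment_fit`.
#' @param n_sim Simulations per observation (`>= 20`; default 250).
#' @param seed Integer seed for the simulation stream.
#' @return List with `residuals` (one value in `[0, 1]` per observation),
#'   `simulations` (n_obs x n_sim matrix) and a zero-count calibration
#'   summary (`observed_zeros`, `simulated_zeros` mean and 2.5/97.5%
#'   quantiles over simulations).
#' @export
scaled_residuals <- function(fit, n_sim = 250, seed = 1) {
  if (n_sim < 20) stop("`n_sim` must be at least 20")
  set.seed(seed)
  design <- fit$design
  all_draws <- as_draws_matrix(fit)
  pick <- sample.int(nrow(all_draws), n_sim, replace = TRUE)
  n <- length(design$y)
  sims <- matrix(NA_integer_, n, n_sim)
  for (s in seq_len(n_sim)) {
    p <- .draw_to_params(all_draws[pick[s], ], design, fit$family)
    mu <- exp(linear_predictor(p, design))
    sims[, s] <- if (fit$family == "nb") {
      stats::rnbinom(n, size = p$phi, mu = mu)
    } else {
      stats::rpois(n, mu)
    }
  }
  n_less <- rowSums(sims < design$y)
  n_equal <- rowSums(sims == design$y)
  resid <- (n_less + stats::runif(n) * (n_equal + 1)) / (n_sim + 1)
  zeros_sim <- colSums(sims == 0)
  list(
    residuals = resid,
    simulations = sims,
    zero_calibration = c(
      observed_zeros = sum(design$y == 0),
      simulated_mean = mean(zeros_sim),
      simulated_lo = unname(stats::quantile(zeros_sim, 0.025)),
      simulated_hi = unname(stats::quantile(zeros_sim, 0.975))
    )
  )
}

#' Compare count families on a design
#'
#' Fits each candidate family by MAP (trait-group intercepts, pooled
#' slopes, family shape parameters; no random effects) and scores it by
#' the uniformity of its randomized quantile residuals
#' (Kolmogorov-Smirnov test) and by zero-count calibration (observed
#' number of zeros against the simulated 95% band). The report is ranked
#' by the KS statistic; families whose residuals depart from uniformity at
#' `alpha` or whose zero count falls outside the band are flagged.
#'
#' @param design A [build_design()] object.
#' @param families Character vector of families (see [count_families()]).
#' @param n_sim Simulations per observation for the residuals.
#' @param alpha Flagging level for the KS test (default 0.01).
#' @param seed Integer seed.
#' @return Data frame `family, logpost, ks_stat, ks_p, observed_zeros,
#'   zero_lo, zero_hi, flagged`, ranked best first; failed fits carry `NA`
#'   and a `flagged` of `TRUE`.
#' @export
compare_families <- function(design, families = count_families(),
                             n_sim = 200, alpha = 0.01, seed = 1) {
  rows <- lapply(families, function(fam) {
    res <- tryCatch({
      fit <- fit_map(design, family = fam, group_slopes = FALSE)
      set.seed(seed)
      famdef <- .count_family(fam)
      mu <- exp(fit$eta)
      n <- length(design$y)
      sims <- matrix(NA_integer_, n, n_sim)
      for (s in seq_len(n_sim)) {
        sims[, s] <- famdef$simulate(n, mu, fit$shape)
      }
      n_less <- rowSums(sims < design$y)
      n_equal <- rowSums(sims == design$y)
      resid <- (n_less + stats::runif(n) * (n_equal + 1)) / (n_sim + 1)
      ks <- suppressWarnings(stats::ks.test(resid, "punif"))
      zs <- colSums(sims == 0)
      zlo <- stats::quantile(zs, 0.025); zhi <- stats::quantile(zs, 0.975)
      obs0 <- sum(design$y == 0)
      data.frame(
        family = fam, logpost = fit$value,
        ks_stat = unname(ks$statistic), ks_p = ks$p.value,
        observed_zeros = obs0, zero_lo = unname(zlo), zero_hi = unname(zhi),
        flagged = ks$p.value < alpha || obs0 < zlo || obs0 > zhi,
        stringsAsFactors = FALSE
      )
    }, error = function(e) {
      data.frame(family = fam, logpost = NA_real_, ks_stat = NA_real_,
                 ks_p = NA_real_, observed_zeros = sum(design$y == 0),
                 zero_lo = NA_real_, zero_hi = NA_real_, flagged = TRUE,
                 stringsAsFactors = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  out[order(out$ks_stat), , drop = FALSE]
}
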