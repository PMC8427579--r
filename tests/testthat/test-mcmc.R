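test_that("fit_posterior is seed-reproducible", {
  cfg <- generator_config(n_plots = 15, n_species = 4, seed = 2)
  syn <- synth_recruitment_data(cfg)
  f1 <- fit_posterior(syn$design, chains = 2, iter = 120, warmup = 60, seed = 5)
  f2 <- fit_posterior(syn$design, chains = 2, iter = 120, warmup = 60, seed = 5)
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_posterior(syn$design, chains = 2, iter = 120, warmup = 60, seed = 6)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("retain thins evenly across chains", {
  cfg <- generator_config(n_plots = 10, n_species = 3, seed = 4)
  syn <- synth_recruitment_data(cfg)
  f <- fit_posterior(syn$design, chains = 2, iter = 200, warmup = 100,
                     retain = 50, seed = 1)
  expect_equal(vapply(f$draws, nrow, 1L), c(25L, 25L))
})

test_that("intercept-only posterior recovers the simulating rate", {
  # single group, no covariates: y ~ NB(exp(b0) * A * dt, phi)
  set.seed(77)
  n_plots <- 60; n_species <- 4
  obs <- expand.grid(plot_id = sprintf("p%02d", 1:n_plots),
                     species = sprintf("s%d", 1:n_species),
                     stringsAsFactors = FALSE)
  obs$period_id <- paste0(obs$plot_id, ":1-2")
  obs$plot_area <- 1; obs$period_length <- 1
  b0_true <- 0.8
  obs$count <- rnbinom(nrow(obs), size = 2, mu = exp(b0_true))
  stand <- data.frame(plot_id = unique(obs$plot_id),
                      period_id = paste0(unique(obs$plot_id), ":1-2"),
                      basal_area = 1, stem_density = 1, sca = 1)
  site <- data.frame(plot_id = unique(obs$plot_id), dds = 1, wb = 1, bs = 1)
  groups <- data.frame(species = unique(obs$species), group = "D2S3")
  d <- build_design(obs, stand, site, groups,
                    drop = c("basal_area", "stem_density", "sca", "dds", "wb", "bs"))
  expect_equal(ncol(d$X), 0L)
  fit <- fit_posterior(d, chains = 2, iter = 800, warmup = 400, seed = 21)
  draws <- as_draws_matrix(fit)
  post_mean <- mean(draws[, "beta0[D2S3]"])
  mc_sd <- sd(draws[, "beta0[D2S3]"])
  expect_lt(abs(post_mean - b0_true), 4 * mc_sd + 0.05)
})

test_that("MAP mode matches a dense grid search on a 1-parameter toy", {
  set.seed(12)
  obs <- data.frame(plot_id = sprintf("p%d", 1:30), species = "s1",
                    period_id = sprintf("p%d:1-2", 1:30),
                    plot_area = 0.5, period_length = 8,
                    count = rpois(30, 1.2))
  stand <- data.frame(plot_id = obs$plot_id, period_id = obs$period_id,
                      basal_area = 1, stem_density = 1, sca = 1)
  site <- data.frame(plot_id = obs$plot_id, dds = 1, wb = 1, bs = 1)
  groups <- data.frame(species = "s1", group = "D2S3")
  d <- build_design(obs, stand, site, groups,
                    drop = c("basal_area", "stem_density", "sca", "dds", "wb", "bs"))
  m <- fit_map(d, family = "poisson")
  expect_length(m$par, 1L)
  # dense grid oracle over the only free parameter
  grid <- seq(-3, 3, by = 1e-4)
  lp <- vapply(grid, function(b) {
    sum(dpois(d$y, exp(d$offset + b), log = TRUE)) + dnorm(b, 0, 5, log = TRUE)
  }, numeric(1))
  expect_equal(unname(m$par[1]), grid[which.max(lp)], tolerance = 1e-3)
  expect_equal(m$value, max(lp), tolerance = 1e-6)
})

test_that("wider priors move the MAP toward the MLE and n shrinks the sd", {
  set.seed(30)
  obs <- data.frame(plot_id = sprintf("p%d", 1:40), species = "s1",
                    period_id = sprintf("p%d:1-2", 1:40),
                    plot_area = 1, period_length = 1,
                    count = rpois(40, 3))
  mk <- function(o) {
    build_design(o,
                 data.frame(plot_id = o$plot_id, period_id = o$period_id,
                            basal_area = 1, stem_density = 1, sca = 1),
                 data.frame(plot_id = o$plot_id, dds = 1, wb = 1, bs = 1),
                 data.frame(species = "s1", group = "D2S3"),
                 drop = c("basal_area", "stem_density", "sca", "dds", "wb", "bs"))
  }
  d <- mk(obs)
  mle <- log(mean(d$y))
  tight <- fit_map(d, family = "poisson", priors = default_priors(beta_sd = 0.1))
  wide <- fit_map(d, family = "poisson", priors = default_priors(beta_sd = 50))
  expect_lt(abs(unname(wide$par[1]) - mle), abs(unname(tight$par[1]) - mle))
  # doubling n shrinks the Laplace sd by ~ sqrt(2)
  obs2 <- rbind(obs, transform(obs, plot_id = paste0(plot_id, "b"),
                               period_id = paste0(period_id, "b")))
  obs2$period_id <- paste0(obs2$plot_id, ":1-2")
  d2 <- mk(obs2)
  l1 <- fit_map(d, family = "poisson", laplace_draws = 4000, seed = 2)
  l2 <- fit_map(d2, family = "poisson", laplace_draws = 4000, seed = 2)
  ratio <- sd(l1$draws[, 1]) / sd(l2$draws[, 1])
  expect_equal(ratio, sqrt(2), tolerance = 0.15)
})

test_that("convergence diagnostics match the textbook split R-hat", {
  set.seed(50)
  # stationary chains: R-hat near 1
  good <- replicate(4, matrix(rnorm(500 * 2), 500, 2,
                              dimnames = list(NULL, c("a", "b"))),
                    simplify = FALSE)
  conv <- convergence(good)
  expect_true(all(conv$rhat < 1.02))
  # shifted chain: clearly detected
  bad <- good
  bad[[1]][, 1] <- bad[[1]][, 1] + 5
  conv_bad <- convergence(bad)
  expect_gt(conv_bad$rhat[conv_bad$parameter == "a"], 1.5)
  expect_lt(conv_bad$rhat[conv_bad$parameter == "b"], 1.02)
  # rank-normalized value equals the textbook formula applied to the
  # rank-normalized draws (independent reimplementation)
  x <- vapply(good, function(d) d[, 1], numeric(500))
  split_x <- cbind(x[1:250, ], x[251:500, ])
  zz <- matrix(qnorm((rank(split_x) - 3 / 8) / (2000 + 1 / 4)), 250, 8)
  expect_equal(conv$rhat[conv$parameter == "a"], oracle_basic_rhat(zz),
               tolerance = 1e-8)
  expect_error(convergence(good[1]), "2 chains")
  # ESS: near-iid chains give large ESS, sticky chains small
  expect_gt(min(conv$ess), 1000)
  ar <- replicate(2, {
    e <- rnorm(600)
    matrix(stats::filter(e, 0.95, method = "recursive"), 600, 1,
           dimnames = list(NULL, "a"))
  }, simplify = FALSE)
  expect_lt(convergence(ar)$ess[1], 300)
})
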