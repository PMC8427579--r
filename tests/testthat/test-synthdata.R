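test_that("generator is deterministic under its seed", {
  cfg <- generator_config(n_plots = 25, n_species = 6, seed = 17)
  a <- generate_covariates(cfg)
  b <- generate_covariates(cfg)
  expect_identical(a, b)
  sa <- synth_recruitment_data(cfg)
  sb <- synth_recruitment_data(cfg)
  expect_identical(sa$design$y, sb$design$y)
  ta <- generate_tree_lists(cfg)
  tb <- generate_tree_lists(cfg)
  expect_identical(ta$trees, tb$trees)
})

test_that("covariate correlations follow the configuration", {
  cv <- ingrowth:::.default_cov_config()
  # identity correlation: near-zero sample correlations at n = 1000
  cv0 <- cv
  cv0$cor <- diag(6); dimnames(cv0$cor) <- dimnames(cv$cor)
  cfg0 <- generator_config(n_plots = 1000, n_species = 6, covariates = cv0,
                           seed = 3)
  t0 <- generate_covariates(cfg0)
  cors <- cor(cbind(t0$stand$basal_area, t0$stand$stem_density, t0$site$dds,
                    t0$site$wb))
  expect_true(max(abs(cors[upper.tri(cors)])) < 0.1)
  # configured dds-wb correlation of 0.5 recovered within 0.1
  cv5 <- cv0
  cv5$cor["dds", "wb"] <- cv5$cor["wb", "dds"] <- 0.5
  cfg5 <- generator_config(n_plots = 1000, n_species = 6, covariates = cv5,
                           seed = 4)
  t5 <- generate_covariates(cfg5)
  expect_equal(cor(t5$site$dds, t5$site$wb), 0.5, tolerance = 0.1)
  # non-positive-definite matrix rejected
  bad <- cv0
  bad$cor[1, 2] <- bad$cor[2, 1] <- 1.2
  expect_error(generator_config(covariates = bad), "positive definite")
})

test_that("simulated counts follow the generative law", {
  # all effects zero, offset 1: mean of Y ~= exp(beta0)
  n <- 10000
  obs <- data.frame(plot_id = sprintf("p%05d", 1:n), species = "s1",
                    period_id = sprintf("p%05d:1-2", 1:n),
                    plot_area = 1, period_length = 1, count = 0L)
  stand <- data.frame(plot_id = obs$plot_id, period_id = obs$period_id,
                      basal_area = 1, stem_density = 1, sca = 1)
  site <- data.frame(plot_id = obs$plot_id, dds = 1, wb = 1, bs = 1)
  groups <- data.frame(species = "s1", group = "D2S3")
  d <- build_design(obs, stand, site, groups,
                    drop = c("basal_area", "stem_density", "sca", "dds", "wb", "bs"))
  truth <- init_params(d)
  truth$beta0[] <- 0.5
  truth$sigma_plot <- 1e-8; truth$sigma_species <- 1e-8
  truth$phi <- 2
  sim <- simulate_counts(d, truth, seed = 5)
  expect_equal(mean(sim$y), exp(0.5), tolerance = 0.05)
  # Poisson limit: variance ~= mean for huge phi
  truth$phi <- 1e8
  simp <- simulate_counts(d, truth, seed = 6)
  expect_equal(var(simp$y), mean(simp$y), tolerance = 0.05)
  # determinism
  expect_identical(simulate_counts(d, truth, seed = 6)$y, simp$y)
})

test_that("default synthetic response is zero-dominated and right-skewed", {
  syn <- synth_recruitment_data(generator_config(n_plots = 150,
                                                 n_species = 10, seed = 21))
  y <- syn$design$y
  expect_equal(median(y), 0)
  expect_gt(mean(y == 0), 0.5)
  expect_gt(max(y), 10)          # long right tail
  expect_gt(mean(y), median(y))  # right skew
})

test_that("tree lists create recruits consistent with their controls", {
  cfg <- generator_config(n_plots = 10, n_species = 5, seed = 31)
  # zero growth, zero in-growth, zero mortality: no recruits anywhere
  tl <- generate_tree_lists(cfg, growth_rate = 1e-9, ingrowth_rate = 1e-9,
                            mortality = 0)
  inv <- inventory_data(tl$trees, tl$plots, dbh_threshold = cfg$design$dbh_threshold)
  tab <- tabulate_recruitment(inv)
  expect_equal(sum(tab$observations$count), 0L)
  # every new tree above the threshold: recruits equal new trees
  tl2 <- generate_tree_lists(cfg, growth_rate = 1e-9, ingrowth_rate = 3,
                             prop_above = 1, mortality = 0)
  inv2 <- inventory_data(tl2$trees, tl2$plots, dbh_threshold = cfg$design$dbh_threshold)
  tab2 <- tabulate_recruitment(inv2)
  n_new <- sum(grepl("_n", tl2$trees$tree_id))
  expect_equal(sum(tab2$observations$count), n_new)
  expect_gt(n_new, 0)
})

test_that("realized stand structure tracks the covariate targets", {
  cfg <- generator_config(n_plots = 40, n_species = 6, seed = 41)
  tl <- generate_tree_lists(cfg)
  inv <- inventory_data(tl$trees, tl$plots, dbh_threshold = cfg$design$dbh_threshold)
  # census-1 basal area per plot vs the generator's target
  t1 <- inv$trees[inv$trees$census_id == 1L, ]
  ba1 <- tapply(pi * (t1$dbh_cm / 200)^2, t1$plot_id, sum)
  area <- tl$plots$plot_area_ha[match(names(ba1), tl$plots$plot_id)]
  target <- tl$tables$stand$basal_area[match(names(ba1), tl$tables$stand$plot_id)]
  rel_err <- abs(ba1 / area - target) / target
  expect_lt(mean(rel_err), 0.2)
})

test_that("trait groups from the generator cover all six archetypes", {
  tabs <- generate_covariates(generator_config(n_plots = 10, n_species = 12,
                                               seed = 51))
  expect_equal(length(unique(tabs$traits$group)), 6)
  expect_true(all(tabs$traits$shade_tol >= 1 & tabs$traits$shade_tol <= 5))
})

test_that("desk-scale recovery harness reports coverage and bias", {
  rec <- recovery_experiment(generator_config(n_plots = 25, n_species = 6),
                             n_replicates = 2, chains = 2, iter = 150,
                             warmup = 80, seed = 3)
  expect_true(all(c("coverage", "bias", "mc_sd", "rmse") %in% names(rec$summary)))
  expect_equal(length(unique(rec$coefficients$replicate)), 2)
  expect_true(rec$overall_coverage >= 0 && rec$overall_coverage <= 1)
  # seeded run is identical
  rec2 <- recovery_experiment(generator_config(n_plots = 25, n_species = 6),
                              n_replicates = 2, chains = 2, iter = 150,
                              warmup = 80, seed = 3)
  expect_identical(rec$summary, rec2$summary)
})
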