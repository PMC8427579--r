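# craft a recruitment_fit with hand-chosen draws over a toy design
fake_fit <- function(design, draw_fun, n_draws = 100, seed = 1) {
  set.seed(seed)
  G <- levels(design$group); J <- levels(design$species)
  I <- levels(design$plot); M <- colnames(design$X)
  pnames <- c(paste0("beta0[", G, "]"),
              paste0("beta[", rep(G, length(M)), ",",
                     rep(M, each = length(G)), "]"),
              paste0("u0_plot[", I, "]"),
              paste0("u0_species[", J, "]"),
              paste0("u_species[", rep(J, length(M)), ",",
                     rep(M, each = length(J)), "]"),
              "sigma[u0_plot]", "sigma[u0_species]",
              paste0("sigma[u_species,", M, "]"), "phi")
  draws <- t(vapply(seq_len(n_draws), function(s) draw_fun(s, pnames),
                    numeric(length(pnames))))
  colnames(draws) <- pnames
  structure(list(draws = list(draws), design = design, family = "nb",
                 config = list(chains = 1)), class = "recruitment_fit")
}

test_that("effect estimates decompose into mean and deviations", {
  d <- toy_design(n_plots = 6, n_species = 4, seed = 1)  # groups D2S1, D2S5
  a <- 0.7
  fit <- fake_fit(d, function(s, pn) {
    v <- setNames(rep(0, length(pn)), pn)
    v["beta[D2S1,basal_area]"] <- a
    v["beta[D2S5,basal_area]"] <- -a
    v[grepl("sigma|phi", pn)] <- 1
    v
  })
  est <- effect_estimates(fit)
  ba <- est[est$variable == "basal_area", ]
  expect_equal(ba$overall_mean, c(0, 0))
  expect_equal(ba$deviation[ba$group == "D2S1"], a)
  expect_equal(ba$deviation[ba$group == "D2S5"], -a)
  expect_true(all(est$dev_lo <= est$deviation & est$deviation <= est$dev_hi))
  # single group: deviations identically zero
  d1 <- toy_design(n_plots = 5, n_species = 2, seed = 2)
  d1$group <- factor(rep("D2S1", length(d1$y)))
  fit1 <- fake_fit(d1, function(s, pn) {
    v <- setNames(rnorm(length(pn), 0, 0.3), pn); v[grepl("sigma|phi", pn)] <- 1; v
  })
  est1 <- effect_estimates(fit1)
  expect_true(all(abs(est1$deviation) < 1e-12))
  # random draws: summaries match a direct quantile oracle
  fitr <- fake_fit(d, function(s, pn) {
    v <- setNames(rnorm(length(pn), 0, 0.5), pn); v[grepl("sigma|phi", pn)] <- 1; v
  }, n_draws = 400)
  estr <- effect_estimates(fitr)
  dr <- as_draws_matrix(fitr)
  B <- dr[, c("beta[D2S1,sca]", "beta[D2S5,sca]")]
  ov <- rowMeans(B)
  row <- estr[estr$variable == "sca" & estr$group == "D2S1", ]
  expect_equal(row$overall_mean, mean(ov))
  expect_equal(row$overall_lo, unname(quantile(ov, 0.025)))
  expect_equal(row$deviation, mean(B[, 1] - ov))
})

test_that("effect curves follow the per-draw evaluation", {
  d <- toy_design(n_plots = 8, n_species = 4, seed = 3)
  fit <- fake_fit(d, function(s, pn) {
    v <- setNames(rep(0, length(pn)), pn)
    v["beta0[D2S1]"] <- rnorm(1, -1, 0.2)
    v["beta[D2S1,basal_area]"] <- rnorm(1, -0.5, 0.1)
    v[grepl("sigma|phi", pn)] <- 1
    v
  }, n_draws = 120)
  cur <- effect_curve(fit, "basal_area", "D2S1", grid_n = 20)
  expect_equal(nrow(cur), 20)
  expect_true(all(cur$mean > 0 & is.finite(cur$mean)))
  # negative coefficient in every draw: strictly decreasing curve
  expect_true(all(diff(cur$mean) < 0))
  # loop oracle
  dr <- as_draws_matrix(fit)
  xz <- (cur$value - d$center["basal_area"]) / d$scale["basal_area"]
  manual <- sapply(seq_along(xz), function(k) {
    mean(exp(dr[, "beta0[D2S1]"] + dr[, "beta[D2S1,basal_area]"] * xz[k]))
  })
  expect_equal(cur$mean, manual)
  # at the covariate mean the curve is exp(beta0) exactly
  at0 <- effect_curve(fit, "basal_area", "D2S1", grid_n = 1)
  mu0 <- mean(exp(dr[, "beta0[D2S1]"] +
                    dr[, "beta[D2S1,basal_area]"] *
                      (at0$value - d$center["basal_area"]) / d$scale["basal_area"]))
  expect_equal(at0$mean, mu0)
  expect_error(effect_curve(fit, "basal_area", "D9S9"), "absent")
  expect_error(effect_curve(fit, "ba_x_density", "D2S1"), "main-effect")
})

test_that("exp(beta0) is reproduced when the focal value sits at the mean", {
  d <- toy_design(n_plots = 8, n_species = 4, seed = 5)
  fit <- fake_fit(d, function(s, pn) {
    v <- setNames(rep(0, length(pn)), pn)
    v["beta0[D2S1]"] <- -0.8
    v["beta[D2S1,dds]"] <- 0.4
    v[grepl("sigma|phi", pn)] <- 1
    v
  }, n_draws = 10)
  # build a curve value exactly at the standardization center
  cur <- effect_curve(fit, "dds", "D2S1", grid_n = 3)
  interp <- approx(cur$value, cur$mean, xout = d$center["dds"])$y
  expect_equal(interp, unname(exp(-0.8)), tolerance = 0.05)
})

test_that("interaction surfaces respect the sign algebra", {
  d <- toy_design(n_plots = 10, n_species = 4, seed = 7)
  fit <- fake_fit(d, function(s, pn) {
    v <- setNames(rep(0, length(pn)), pn)
    v["beta0[D2S1]"] <- -1
    v["beta[D2S1,basal_area]"] <- -0.6
    v["beta[D2S1,stem_density]"] <- 0.3
    v["beta[D2S1,ba_x_density]"] <- 0.2
    v[grepl("sigma|phi", pn)] <- 1
    v
  }, n_draws = 50)
  surf <- interaction_surface(fit, "D2S1", grid_n = 15)
  expect_equal(sort(unique(surf$density_percentile)), c(10, 30, 50, 70, 90))
  expect_true(all(surf$mean > 0))
  # positive interaction + negative BA main effect: the BA slope (log
  # scale) is less negative at higher stem density
  slopes <- sapply(split(surf, surf$density_percentile), function(s) {
    coef(lm(log(s$mean) ~ s$basal_area))[2]
  })
  expect_true(all(diff(slopes[order(as.numeric(names(slopes)))]) > 0))
  # zero interaction: parallel curves on the log scale
  fit0 <- fake_fit(d, function(s, pn) {
    v <- setNames(rep(0, length(pn)), pn)
    v["beta0[D2S1]"] <- -1
    v["beta[D2S1,basal_area]"] <- -0.6
    v["beta[D2S1,stem_density]"] <- 0.3
    v[grepl("sigma|phi", pn)] <- 1
    v
  }, n_draws = 20)
  surf0 <- interaction_surface(fit0, "D2S1", grid_n = 10)
  gaps <- sapply(split(surf0, surf0$density_percentile), function(s) log(s$mean))
  rel <- gaps - gaps[, 1]
  expect_true(all(apply(rel, 2, function(col) diff(range(col)) < 1e-10)))
  # loop oracle on one percentile
  dr <- as_draws_matrix(fit)
  s50 <- surf[surf$density_percentile == 50, ]
  dz <- (s50$stem_density[1] - d$center["stem_density"]) / d$scale["stem_density"]
  bz <- (s50$basal_area - d$center["basal_area"]) / d$scale["basal_area"]
  manual <- sapply(bz, function(b) {
    mean(exp(dr[, "beta0[D2S1]"] + dr[, "beta[D2S1,basal_area]"] * b +
               dr[, "beta[D2S1,stem_density]"] * dz +
               dr[, "beta[D2S1,ba_x_density]"] * b * dz))
  })
  expect_equal(s50$mean, manual)
})
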