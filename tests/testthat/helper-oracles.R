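# Independent oracles: hand-coded from the published formulas, kept free
# of the package's implementation paths.

# Thornthwaite monthly PET (1948), straightforward transcription
oracle_thornthwaite <- function(tmean12, latitude) {
  heat <- sum((pmax(tmean12, 0) / 5)^1.514)
  if (heat == 0) return(rep(0, 12))
  a <- 675e-9 * heat^3 - 771e-7 * heat^2 + 1792e-5 * heat + 0.49239
  mdays <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  mid <- cumsum(c(0, mdays[-12])) + mdays %/% 2
  decl <- 0.409 * sin(2 * pi * mid / 365 - 1.39)
  cosw <- pmin(pmax(-tan(latitude * pi / 180) * tan(decl), -1), 1)
  daylen <- 24 / pi * acos(cosw)
  pet <- ifelse(tmean12 <= 0, 0,
    ifelse(tmean12 < 26.5,
      16 * (10 * tmean12 / heat)^a,
      -415.85 + 32.24 * tmean12 - 0.43 * tmean12^2
    )
  )
  pet * (daylen / 12) * (mdays / 30)
}

# Gelman-Rubin statistic, textbook form, on an iterations x chains matrix
# (chains already split / transformed by the caller)
oracle_basic_rhat <- function(z) {
  m <- nrow(z)
  W <- mean(apply(z, 2, var))
  B <- m * var(colMeans(z))
  sqrt(((m - 1) / m * W + B / m) / W)
}

# daily climate frame covering whole calendar years
make_climate <- function(years, tmean_fun, precip_fun, plot_id = "p1") {
  dates <- seq(as.Date(sprintf("%d-01-01", min(years))),
               as.Date(sprintf("%d-12-31", max(years))), by = "day")
  data.frame(
    plot_id = plot_id, date = as.character(dates),
    tmean_c = tmean_fun(dates), precip_mm = precip_fun(dates),
    stringsAsFactors = FALSE
  )
}

# minimal hand-built design for likelihood / effects tests
toy_design <- function(n_plots = 4, n_species = 3, seed = 1, counts = NULL) {
  set.seed(seed)
  plots <- sprintf("p%d", seq_len(n_plots))
  species <- sprintf("s%d", seq_len(n_species))
  obs <- expand.grid(plot_id = plots, species = species,
                     stringsAsFactors = FALSE)
  obs$period_id <- paste0(obs$plot_id, ":1-2")
  obs$count <- if (is.null(counts)) rpois(nrow(obs), 1) else counts
  obs$plot_area <- 0.25
  obs$period_length <- 10
  stand <- data.frame(
    plot_id = plots, period_id = paste0(plots, ":1-2"),
    basal_area = runif(n_plots, 10, 60),
    stem_density = runif(n_plots, 100, 1500),
    sca = runif(n_plots, 1, 5)
  )
  site <- data.frame(
    plot_id = plots, dds = runif(n_plots, 1000, 3000),
    wb = runif(n_plots, -200, 500), bs = runif(n_plots, 10, 45)
  )
  groups <- data.frame(
    species = species,
    group = rep(c("D2S1", "D2S5"), length.out = n_species)
  )
  build_design(obs, stand, site, groups)
}

# small synthetic fit used by effects/diagnostics tests
tiny_fit <- function(n_plots = 30, n_species = 6, seed = 3, ...) {
  cfg <- generator_config(n_plots = n_plots, n_species = n_species, seed = seed)
  syn <- synth_recruitment_data(cfg)
  fit_posterior(syn$design, chains = 2, iter = 200, warmup = 100,
                seed = seed, ...)
}

# independent brute-force log posterior: explicit loop over rows and
# random-effect entries
oracle_log_posterior <- function(p, d, pr) {
  total <- 0
  for (r in seq_len(length(d$y))) {
    g <- as.character(d$group[r]); i <- as.character(d$plot[r])
    j <- as.character(d$species[r])
    eta <- d$offset[r] + p$beta0[g] + p$u0_plot[i] + p$u0_species[j]
    for (m in d$vars) {
      eta <- eta + (p$beta[g, m] + p$u_species[j, m]) * d$X[r, m]
    }
    mu <- exp(eta)
    total <- total + lgamma(d$y[r] + p$phi) - lgamma(p$phi) -
      lgamma(d$y[r] + 1) + p$phi * log(p$phi / (mu + p$phi)) +
      d$y[r] * log(mu / (mu + p$phi))
  }
  for (i in names(p$u0_plot)) {
    total <- total + dnorm(p$u0_plot[i], 0, p$sigma_plot, log = TRUE)
  }
  for (j in names(p$u0_species)) {
    total <- total + dnorm(p$u0_species[j], 0, p$sigma_species, log = TRUE)
  }
  for (j in rownames(p$u_species)) for (m in d$vars) {
    total <- total + dnorm(p$u_species[j, m], 0, p$sigma_slope[m], log = TRUE)
  }
  for (g in names(p$beta0)) total <- total + dnorm(p$beta0[g], 0, pr$beta_sd, log = TRUE)
  for (g in rownames(p$beta)) for (m in d$vars) {
    total <- total + dnorm(p$beta[g, m], 0, pr$beta_sd, log = TRUE)
  }
  total +
    sum(log(2) + dnorm(c(p$sigma_plot, p$sigma_species, p$sigma_slope), 0,
                       pr$sigma_sd, log = TRUE)) +
    dgamma(p$phi, pr$phi_shape, rate = pr$phi_rate, log = TRUE)
}

random_params <- function(d, seed) {
  set.seed(seed)
  p <- init_params(d)
  p$beta0[] <- rnorm(length(p$beta0), 0, 0.5)
  p$beta[] <- rnorm(length(p$beta), 0, 0.3)
  p$u0_plot[] <- rnorm(length(p$u0_plot), 0, 0.4)
  p$u0_species[] <- rnorm(length(p$u0_species), 0, 0.4)
  p$u_species[] <- rnorm(length(p$u_species), 0, 0.2)
  p$sigma_plot <- runif(1, 0.2, 1); p$sigma_species <- runif(1, 0.2, 1)
  p$sigma_slope[] <- runif(length(p$sigma_slope), 0.1, 0.5)
  p$phi <- runif(1, 0.5, 3)
  p
}

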