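# Synthetic-inventory generator. Emulates the statistical structure the
# analysis assumes: four inventory designs differing in calipering
# threshold, plot size and period length; correlated plot covariates on
# realistic scales; a species pool with (drought, shade) tolerance traits
# clustered into six groups; and recruitment counts drawn from the
# hierarchical NB generative model with known parameters. All randomness
# flows from one seed via fixed sub-stream offsets (+1 covariates,
# +2 counts, +3 tree lists).

# Inventory design presets: calipering threshold [cm], plot-size and
# period-length [yr] samplers mimicking the four source inventories.
.design_presets <- list(
  CH_FR = list(
    dbh_threshold = 4,
    r_area = function(n) pmin(pmax(stats::rlnorm(n, log(0.35), 0.8), 0.03), 3.47),
    r_period = function(n) pmin(pmax(stats::rnorm(n, 12.2, 4), 1), 27)
  ),
  GER_FR = list(
    dbh_threshold = 7,
    r_area = function(n) sample(c(0.05, 0.1), n, replace = TRUE, prob = c(0.06, 0.94)),
    r_period = function(n) pmin(pmax(stats::rnorm(n, 14.8, 5), 9), 27)
  ),
  FLAN_NFI = list(
    dbh_threshold = 7,
    r_area = function(n) sample(c(0.02, 0.03), n, replace = TRUE, prob = c(0.05, 0.95)),
    r_period = function(n) pmin(pmax(stats::rnorm(n, 14.7, 3), 10), 22)
  ),
  CH_NFI = list(
    dbh_threshold = 12,
    r_area = function(n) rep(0.02, n),
    r_period = function(n) pmin(pmax(stats::rnorm(n, 9.7, 3), 3), 30)
  )
)

# Default covariate distribution: means/sds span the published summary
# ranges of a mixed central-European inventory; the correlation couples
# basal area with stem density and SCA (stand development) and degree-days
# negatively with water balance (warm = dry).
.cov_names <- c("basal_area", "stem_density", "sca", "dds", "wb", "bs")

.default_cov_config <- function() {
  R <- diag(6)
  dimnames(R) <- list(.cov_names, .cov_names)
  R["basal_area", "stem_density"] <- R["stem_density", "basal_area"] <- 0.5
  R["basal_area", "sca"] <- R["sca", "basal_area"] <- 0.3
  R["stem_density", "sca"] <- R["sca", "stem_density"] <- 0.1
  R["dds", "wb"] <- R["wb", "dds"] <- -0.4
  R["dds", "bs"] <- R["bs", "dds"] <- -0.2
  R["wb", "bs"] <- R["bs", "wb"] <- 0.2
  list(
    mean = c(basal_area = 35, stem_density = 900, sca = 3.5,
             dds = 2500, wb = 120, bs = 32),
    sd = c(basal_area = 12, stem_density = 500, sca = 0.9,
           dds = 500, wb = 280, bs = 6),
    cor = R,
    lower = c(basal_area = 1, stem_density = 20, sca = 1,
              dds = 500, wb = -380, bs = 9),
    upper = c(basal_area = 100, stem_density = 3200, sca = 5,
              dds = 4400, wb = 2150, bs = 47)
  )
}

#' Configuration for the synthetic-inventory generator
#'
#' @param n_plots Number of plots (default 200).
#' @param n_species Species-pool size (default 10).
#' @param n_periods Census periods per plot (default 1).
#' @param preset Inventory design preset: `"CH_FR"`, `"GER_FR"`,
#'   `"FLAN_NFI"` or `"CH_NFI"`; sets the calipering threshold and the
#'   plot-size / period-length distributions.
#' @param covariates Covariate distribution (means, sds, correlation,
#'   clipping bounds); see the default for the structure.
#' @param seed Master seed; sub-streams derive from it.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_plots = 200, n_species = 10, n_periods = 1,
                             preset = "CH_FR",
                             covariates = .default_cov_config(), seed = 1) {
  stopifnot(n_plots >= 1, n_species >= 1, n_periods >= 1,
            preset %in% names(.design_presets))
  ev <- eigen(covariates$cor, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("covariate correlation matrix is not positive definite")
  structure(list(
    n_plots = n_plots, n_species = n_species, n_periods = n_periods,
    preset = preset, design = .design_presets[[preset]],
    covariates = covariates, seed = as.integer(seed)
  ), class = "generator_config")
}

# archetypal (drought, shade) tolerance profiles used to seed the species
# pool; identical to the default k-means centroids
.trait_archetypes <- function() default_centroids()

#' Generate correlated plot covariates, species traits and trait groups
#'
#' Plot covariates are multivariate normal with the configured correlation,
#' clipped to plausible ranges. Species tolerance traits scatter around the
#' six archetypal (drought, shade) profiles, cycled so every archetype is
#' populated, and are grouped with the seeded k-means of the traits module.
#'
#' @param config A [generator_config()].
#' @return List with `plots`, `periods` (plot x period skeleton with areas
#'   and period lengths), `stand` (per plot-period), `site` (per plot),
#'   `traits` (with `group` labels) and `observations` (zero-count
#'   skeleton, one row per plot-period-species).
#' @export
generate_covariates <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed + 1L)
  cv <- config$covariates
  n <- config$n_plots * config$n_periods
  L <- chol(cv$cor)
  Z <- matrix(stats::rnorm(n * 6), n, 6) %*% L
  raw <- sweep(sweep(Z, 2, cv$sd[.cov_names], "*"), 2, cv$mean[.cov_names], "+")
  colnames(raw) <- .cov_names
  raw <- pmin(pmax(raw, rep(cv$lower[.cov_names], each = n)),
              rep(cv$upper[.cov_names], each = n))

  plot_id <- sprintf("p%04d", seq_len(config$n_plots))
  period_id <- as.vector(outer(plot_id, seq_len(config$n_periods),
                               function(p, k) paste0(p, ":", k, "-", k + 1)))
  row_plot <- rep(plot_id, config$n_periods)
  plots <- data.frame(
    plot_id = plot_id,
    plot_area_ha = config$design$r_area(config$n_plots),
    stringsAsFactors = FALSE
  )
  periods <- data.frame(
    plot_id = row_plot, period_id = period_id,
    plot_area = plots$plot_area_ha[match(row_plot, plots$plot_id)],
    period_length = config$design$r_period(n),
    stringsAsFactors = FALSE
  )
  stand <- data.frame(
    plot_id = row_plot, period_id = period_id,
    basal_area = raw[, "basal_area"], stem_density = raw[, "stem_density"],
    sca = raw[, "sca"], stringsAsFactors = FALSE
  )
  # site covariates vary between plots only: take each plot's first period
  first <- match(plot_id, row_plot)
  site <- data.frame(
    plot_id = plot_id, dds = raw[first, "dds"], wb = raw[first, "wb"],
    bs = raw[first, "bs"], stringsAsFactors = FALSE
  )

  arch <- .trait_archetypes()
  k <- (seq_len(config$n_species) - 1L) %% nrow(arch) + 1L
  traits <- data.frame(
    species = sprintf("sp%02d", seq_len(config$n_species)),
    genus = sprintf("g%02d", (seq_len(config$n_species) - 1L) %% 4L + 1L),
    shade_tol = pmin(pmax(arch[k, "shade_tol"] + stats::rnorm(config$n_species, 0, 0.35), 1), 5),
    drought_tol = pmin(pmax(arch[k, "drought_tol"] + stats::rnorm(config$n_species, 0, 0.35), 1), 5),
    stringsAsFactors = FALSE
  )
  traits$sca <- pmin(pmax(traits$shade_tol + stats::rnorm(config$n_species, 0, 0.5), 1), 5)
  traits <- build_trait_groups(traits)

  observations <- merge(periods, data.frame(species = traits$species),
                        by = NULL, sort = FALSE)
  observations <- observations[order(observations$period_id, observations$species), ]
  rownames(observations) <- NULL
  observations$count <- 0L

  list(plots = plots, periods = periods, stand = stand, site = site,
       traits = traits, observations = observations)
}

# map a D#S# label to the nearest archetype's effect entry
.match_archetype <- function(labels) {
  arch_lab <- c("D2S1", "D5S1", "D2S3", "D4S3", "D3S4", "D2S5")
  d <- as.integer(sub("^D(\\d)S(\\d).*$", "\\1", labels))
  s <- as.integer(sub("^D(\\d)S(\\d).*$", "\\2", labels))
  arch <- .trait_archetypes()
  vapply(seq_along(labels), function(i) {
    if (labels[i] %in% arch_lab) return(match(labels[i], arch_lab))
    which.min((arch[, "drought_tol"] - d[i])^2 + (arch[, "shade_tol"] - s[i])^2)
  }, integer(1))
}

#' Default "true" parameters for simulation
#'
#' Group-level effects mirror the qualitative findings the model is meant
#' to recover: basal area and SCA depress recruitment of light-demanding
#' groups while SCA favors very shade-tolerant ones; stem density and
#' degree-days act positively everywhere; water-related effects are small;
#' the basal-area x stem-density interaction is positive. Illustrative, not
#' calibrated.
#'
#' @param design A [build_design()] object (group levels and variables are
#'   read from it).
#' @param sigma_plot,sigma_species,sigma_slope,phi Variance components and
#'   NB dispersion of the generative model.
#' @return A parameter list as in [init_params()].
#' @export
default_true_parameters <- function(design, sigma_plot = 0.5,
                                    sigma_species = 0.3, sigma_slope = 0.1,
                                    phi = 1) {
  effects <- list(  # per archetype D2S1, D5S1, D2S3, D4S3, D3S4, D2S5
    basal_area = c(-0.8, -0.9, -0.35, -0.3, -0.15, -0.1),
    stem_density = rep(0.3, 6),
    sca = c(-0.8, -0.9, -0.3, -0.25, 0.3, 0.6),
    dds = rep(0.25, 6),
    wb = rep(0.05, 6),
    bs = rep(0.1, 6),
    ba_x_density = rep(0.15, 6),
    wb_x_bs = rep(0.05, 6)
  )
  p <- init_params(design)
  ai <- .match_archetype(levels(design$group))
  p$beta0[] <- -2.5
  for (v in colnames(p$beta)) p$beta[, v] <- effects[[v]][ai]
  p$sigma_plot <- sigma_plot
  p$sigma_species <- sigma_species
  p$sigma_slope[] <- sigma_slope
  p$phi <- phi
  p
}

#' Simulate counts from the generative recruitment model
#'
#' Draws plot and species random effects from their normal laws, computes
#' the expected count through the model's linear predictor (offsets
#' included) and draws negative-binomial counts.
#'
#' @param design A [build_design()] object (its `y` is ignored).
#' @param truth Parameter list (e.g. [default_true_parameters()]); its
#'   random-effect entries are overwritten by fresh draws.
#' @param seed Integer seed.
#' @return List with `y` (integer counts), `params` (truth with the drawn
#'   random effects) and `mu` (expected counts).
#' @export
simulate_counts <- function(design, truth, seed = 1) {
  set.seed(seed)
  p <- truth
  p$u0_plot[] <- stats::rnorm(length(p$u0_plot), 0, p$sigma_plot)
  p$u0_species[] <- stats::rnorm(length(p$u0_species), 0, p$sigma_species)
  p$u_species[] <- stats::rnorm(length(p$u_species), 0,
                                rep(p$sigma_slope, each = nrow(p$u_species)))
  mu <- exp(linear_predictor(p, design))
  if (any(!is.finite(mu))) stop("non-finite expected counts in simulation")
  y <- stats::rnbinom(length(mu), size = p$phi, mu = mu)
  list(y = y, params = p, mu = mu)
}

#' Generate a complete synthetic recruitment data set
#'
#' Covariates, trait groups, design matrix and NB counts from known
#' parameters, ready to fit. The response in the returned design and
#' observation table is the simulated count.
#'
#' @param config A [generator_config()].
#' @param truth Optional parameter list; default
#'   [default_true_parameters()] with its default variance components.
#' @param drop Passed to [build_design()].
#' @return List with `design` (response filled in), `truth` (including the
#'   drawn random effects), and the generator `tables`.
#' @export
synth_recruitment_data <- function(config = generator_config(), truth = NULL,
                                   drop = NULL) {
  tabs <- generate_covariates(config)
  design <- build_design(tabs$observations, tabs$stand, tabs$site,
                         tabs$traits, drop = drop)
  if (is.null(truth)) truth <- default_true_parameters(design)
  sim <- simulate_counts(design, truth, seed = config$seed + 2L)
  design$y <- sim$y
  design$obs$count <- sim$y
  tabs$observations$count <- sim$y
  list(design = design, truth = sim$params, tables = tabs)
}

#' Generate synthetic repeated tree lists
#'
#' Builds census-1 tree lists whose stem density and basal area match the
#' generated stand covariates, grows the trees with positive increments,
#' applies light mortality, and adds new small trees so that genuine
#' recruits cross the calipering threshold at census 2. Output feeds
#' [inventory_data()] through the same tables as real data.
#'
#' @param config A [generator_config()].
#' @param tables Output of [generate_covariates()] (generated if missing).
#' @param growth_rate Mean annual diameter increment, cm/yr (default 0.2).
#' @param ingrowth_rate New trees per ha per year crossing or approaching
#'   the threshold (default 2).
#' @param prop_above Fraction of new trees that cross the threshold by
#'   census 2 (the rest enter as saplings below it; default 0.7).
#' @param mortality Annual mortality probability (default 0.01).
#' @return List with `trees` (both censuses), `plots`, and `tables`.
#' @export
generate_tree_lists <- function(config = generator_config(), tables = NULL,
                                growth_rate = 0.2, ingrowth_rate = 2,
                                prop_above = 0.7, mortality = 0.01) {
  if (is.null(tables)) tables <- generate_covariates(config)
  set.seed(config$seed + 3L)
  thr <- config$design$dbh_threshold
  species <- tables$traits$species
  out <- vector("list", nrow(tables$periods))
  for (r in seq_len(nrow(tables$periods))) {
    pd <- tables$periods[r, ]
    st <- tables$stand[r, ]
    area <- pd$plot_area
    years <- pd$period_length
    n1 <- max(1L, round(st$stem_density * area))
    qmd <- sqrt(st$basal_area * 40000 / (pi * st$stem_density))
    dbh1 <- thr + stats::rgamma(n1, shape = 3, scale = max(qmd - thr, 0.5) / 3)
    # rescale toward the basal-area target (keeps all stems above threshold)
    f <- sqrt(st$basal_area * area / sum(pi * (dbh1 / 200)^2))
    dbh1 <- pmax(dbh1 * f, thr + 0.05)
    sp_w <- stats::rgamma(length(species), 1)  # plot-level composition
    sp1 <- sample(species, n1, replace = TRUE, prob = sp_w / sum(sp_w))
    id1 <- sprintf("%s_t%04d", pd$plot_id, seq_len(n1))

    alive <- stats::runif(n1) > 1 - (1 - mortality)^years
    growth <- stats::rgamma(n1, shape = 2, scale = growth_rate * years / 2)
    n_new <- stats::rpois(1, ingrowth_rate * area * years)
    dbh_new <- numeric(0); sp_new <- character(0); id_new <- character(0)
    if (n_new > 0) {
      big <- stats::runif(n_new) <= prop_above
      dbh_new <- ifelse(big, thr + stats::rexp(n_new, 1 / 1.5),
                        stats::runif(n_new, thr * 0.3, thr * 0.95))
      sp_new <- sample(species, n_new, replace = TRUE, prob = sp_w / sum(sp_w))
      id_new <- sprintf("%s_n%04d", pd$plot_id, seq_len(n_new))
    }
    date1 <- as.Date("2000-01-01")
    date2 <- date1 + round(years * 365.25)
    out[[r]] <- rbind(
      data.frame(plot_id = pd$plot_id, census_id = 1L,
                 census_date = date1, tree_id = id1, species = sp1,
                 dbh_cm = dbh1, stringsAsFactors = FALSE),
      data.frame(plot_id = pd$plot_id, census_id = 2L,
                 census_date = date2, tree_id = id1[alive],
                 species = sp1[alive], dbh_cm = (dbh1 + growth)[alive],
                 stringsAsFactors = FALSE),
      if (n_new > 0) {
        data.frame(plot_id = pd$plot_id, census_id = 2L,
                   census_date = date2, tree_id = id_new, species = sp_new,
                   dbh_cm = dbh_new, stringsAsFactors = FALSE)
      }
    )
  }
  trees <- do.call(rbind, out)
  rownames(trees) <- NULL
  list(trees = trees, plots = tables$plots, tables = tables)
}

#' Parameter-recovery experiment
#'
#' Replicated simulate-fit-score loops over one fixed synthetic design:
#' the covariates, species pool and trait groups are generated once from
#' the configuration (so the parameter structure is identical across
#' replicates), and each replicate draws fresh random effects and counts
#' from the known parameters, fits the model, and scores the trait-group
#' coefficients (95% credible-interval coverage, bias, RMSE) plus the
#' dispersion.
#'
#' @param config A [generator_config()]; fixes the design.
#' @param n_replicates Number of replicates (default 20).
#' @param chains,iter,warmup Passed to [fit_posterior()].
#' @param seed Master seed (per-replicate seeds derive from it).
#' @return List with `coefficients` (per replicate x coefficient: truth,
#'   posterior mean, CI, covered), `summary` (coverage, bias, RMSE per
#'   coefficient), `overall_coverage`, and `failures`.
#' @export
recovery_experiment <- function(config = generator_config(n_plots = 100,
                                                          n_species = 12),
                                n_replicates = 20, chains = 2, iter = 800,
                                warmup = 400, seed = 1) {
  tabs <- generate_covariates(config)
  design <- build_design(tabs$observations, tabs$stand, tabs$site, tabs$traits)
  truth <- default_true_parameters(design)
  G <- levels(design$group)
  cols <- c(paste0("beta0[", G, "]"),
            paste0("beta[", rep(G, ncol(design$X)), ",",
                   rep(colnames(design$X), each = length(G)), "]"),
            "phi")
  truth_vec <- c(truth$beta0, as.vector(truth$beta), truth$phi)
  rows <- list()
  failures <- character(0)
  for (r in seq_len(n_replicates)) {
    rep_seed <- as.integer(seed + 131L * r)
    res <- tryCatch({
      sim <- simulate_counts(design, truth, seed = rep_seed)
      design$y <- sim$y
      fit <- fit_posterior(design, chains = chains, iter = iter,
                           warmup = warmup, seed = rep_seed)
      draws <- as_draws_matrix(fit)
      est <- colMeans(draws[, cols, drop = FALSE])
      lo <- apply(draws[, cols, drop = FALSE], 2, stats::quantile, 0.025)
      hi <- apply(draws[, cols, drop = FALSE], 2, stats::quantile, 0.975)
      data.frame(replicate = r, parameter = cols, truth = truth_vec,
                 estimate = est, lo = lo, hi = hi,
                 covered = truth_vec >= lo & truth_vec <= hi,
                 row.names = NULL, stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("replicate %d: %s", r, conditionMessage(res)))
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  coefs <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(coefs, coefs$parameter), function(d) {
    data.frame(parameter = d$parameter[1],
               coverage = mean(d$covered),
               bias = mean(d$estimate - d$truth),
               mc_sd = stats::sd(d$estimate),
               rmse = sqrt(mean((d$estimate - d$truth)^2)),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  beta_rows <- grepl("^beta", coefs$parameter)
  list(coefficients = coefs, summary = agg,
       overall_coverage = mean(coefs$covered[beta_rows]),
       failures = failures)
}
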