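#' Build the standardized design for the recruitment model
#'
#' Joins recruitment observations with stand, site and trait-group tables,
#' z-standardizes the six main covariates (basal area, stem density, SCA,
#' degree-day sum, water balance, bucket size) over observation rows, forms
#' the two stated interactions (basal area x stem density, water balance x
#' bucket size) as products of the standardized mains, and attaches the
#' exposure offset `log(plot_area * period_length)`.
#'
#' @param observations Data frame `plot_id, period_id, species, count,
#'   plot_area, period_length` (one row per plot x period x species).
#' @param stand Data frame `plot_id, period_id, basal_area, stem_density,
#'   sca`.
#' @param site Data frame `plot_id, dds, wb, bs`.
#' @param groups Data frame `species, group` mapping species to trait-group
#'   labels (e.g. from [build_trait_groups()]).
#' @param drop Character vector of main-effect names to drop, e.g. `"wb"`
#'   for data sets where water balance is collinear with the degree-day sum;
#'   dropping `wb` or `bs` also drops the `wb_x_bs` interaction, dropping
#'   `basal_area` or `stem_density` drops `ba_x_density`.
#' @return An object of class `recruitment_design`: list with the response
#'   `y`, model matrix `X` (standardized mains then interactions), `offset`,
#'   factors `plot`, `species`, `group`, the variable names, the raw
#'   (unstandardized) mains and the standardization parameters.
#' @export
build_design <- function(observations, stand, site, groups, drop = NULL) {
  need_obs <- c("plot_id", "period_id", "species", "count", "plot_area",
                "period_length")
  stopifnot(all(need_obs %in% names(observations)))
  obs <- observations

  st_key <- paste(stand$plot_id, stand$period_id)
  m_st <- match(paste(obs$plot_id, obs$period_id), st_key)
  if (anyNA(m_st)) {
    stop("missing stand covariates for plot/period: ",
         paste(unique(paste(obs$plot_id, obs$period_id)[is.na(m_st)]),
               collapse = ", "))
  }
  m_si <- match(obs$plot_id, site$plot_id)
  if (anyNA(m_si)) {
    stop("missing site environment for plot: ",
         paste(unique(obs$plot_id[is.na(m_si)]), collapse = ", "))
  }
  m_gr <- match(obs$species, groups$species)
  if (anyNA(m_gr)) {
    stop("missing trait group for species: ",
         paste(unique(obs$species[is.na(m_gr)]), collapse = ", "))
  }

  mains <- c("basal_area", "stem_density", "sca", "dds", "wb", "bs")
  raw <- cbind(
    basal_area = stand$basal_area[m_st],
    stem_density = stand$stem_density[m_st],
    sca = stand$sca[m_st],
    dds = site$dds[m_si],
    wb = site$wb[m_si],
    bs = site$bs[m_si]
  )
  mains <- setdiff(mains, drop)
  raw <- raw[, mains, drop = FALSE]
  if (anyNA(raw)) stop("NA covariate values in the design")

  center <- colMeans(raw)
  scale <- apply(raw, 2, stats::sd)
  if (any(scale == 0)) {
    stop("zero-variance covariate column(s): ",
         paste(mains[scale == 0], collapse = ", "))
  }
  Z <- sweep(sweep(raw, 2, center), 2, scale, "/")

  inter <- NULL
  if (all(c("basal_area", "stem_density") %in% mains)) {
    inter <- cbind(inter, ba_x_density = Z[, "basal_area"] * Z[, "stem_density"])
  }
  if (all(c("wb", "bs") %in% mains)) {
    inter <- cbind(inter, wb_x_bs = Z[, "wb"] * Z[, "bs"])
  }
  X <- cbind(Z, inter)

  offset <- log(obs$plot_area * obs$period_length)
  if (any(!is.finite(offset))) stop("non-positive plot_area or period_length")

  structure(list(
    y = as.integer(obs$count),
    X = X,
    offset = offset,
    plot = factor(obs$plot_id),
    species = factor(obs$species),
    group = factor(groups$group[m_gr]),
    vars = colnames(X),
    mains = mains,
    raw = raw,
    center = center,
    scale = scale,
    obs = obs
  ), class = "recruitment_design")
}

#' @export
print.recruitment_design <- function(x, ...) {
  cat(sprintf(
    "<recruitment_design> %d rows, %d plots, %d species, %d groups; vars: %s\n",
    length(x$y), nlevels(x$plot), nlevels(x$species), nlevels(x$group),
    paste(x$vars, collapse = ", ")
  ))
  invisible(x)
}

#' Variance inflation factors
#'
#' `VIF_m = 1/(1 - R^2_m)` where `R^2_m` is from the least-squares
#' regression of column `m` on the remaining columns (with intercept).
#' Exactly collinear columns report `Inf`.
#'
#' @param x A `recruitment_design` (its main-effect columns are used) or a
#'   numeric matrix with at least two columns.
#' @return Named vector of VIFs.
#' @export
vif <- function(x) {
  X <- if (inherits(x, "recruitment_design")) x$X[, x$mains, drop = FALSE] else as.matrix(x)
  if (ncol(X) < 2L) stop("need at least two columns")
  out <- vapply(seq_len(ncol(X)), function(m) {
    fit <- stats::lm.fit(cbind(1, X[, -m, drop = FALSE]), X[, m])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, m] - mean(X[, m]))^2)
    if (tss == 0) return(Inf)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- colnames(X)
  out
}
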