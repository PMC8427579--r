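#' Fill missing species traits from genus means
#'
#' Species recorded at genus level (or lacking trait values) receive the
#' arithmetic mean of each trait over congeneric species present in the
#' trait table.
#'
#' @param traits Data frame `species, genus, shade_tol, drought_tol, sca`
#'   (tolerances on the 1-5 scale; `NA` where unknown).
#' @return The trait table with `NA` tolerances replaced by genus means.
#' @export
genus_fallback <- function(traits) {
  need <- c("species", "genus", "shade_tol", "drought_tol", "sca")
  stopifnot(all(need %in% names(traits)))
  for (col in c("shade_tol", "drought_tol", "sca")) {
    miss <- which(is.na(traits[[col]]))
    for (r in miss) {
      g <- traits$genus[r]
      vals <- traits[[col]][traits$genus == g & !is.na(traits[[col]])]
      if (length(vals) == 0L) {
        stop(sprintf("no %s value available for species '%s' (genus '%s')",
                     col, traits$species[r], g))
      }
      traits[[col]][r] <- mean(vals)
    }
  }
  traits
}

#' Scale tolerance traits to mean 0 and standard deviation 2
#'
#' Centers each tolerance column and rescales it to a population (divide by
#' n) standard deviation of exactly 2, the convention under which a
#' symmetric pair `{1, 5}` maps to `{-2, +2}`.
#'
#' @param traits Data frame with complete `shade_tol` and `drought_tol`.
#' @return The table with added columns `drought_z`, `shade_z` and an
#'   attribute `scaling` (per-trait center and scale) used to place initial
#'   centroids on the same scale.
#' @export
scale_traits <- function(traits) {
  stopifnot(all(c("shade_tol", "drought_tol") %in% names(traits)))
  if (anyNA(traits$shade_tol) || anyNA(traits$drought_tol)) {
    stop("missing tolerance values; run genus_fallback() first")
  }
  sc <- lapply(traits[c("drought_tol", "shade_tol")], function(x) {
    s <- sqrt(mean((x - mean(x))^2))
    if (s == 0) stop("constant trait column cannot be scaled")
    list(center = mean(x), scale = s / 2)
  })
  traits$drought_z <- (traits$drought_tol - sc$drought_tol$center) / sc$drought_tol$scale
  traits$shade_z <- (traits$shade_tol - sc$shade_tol$center) / sc$shade_tol$scale
  attr(traits, "scaling") <- sc
  traits
}

#' Default initial k-means centroids on the tolerance scale
#'
#' Six starting points in (drought tolerance, shade tolerance) space on the
#' original 1-5 scale: four along the diagonal from very drought-tolerant /
#' light-demanding to drought-intolerant / very shade-tolerant, plus two
#' drought-intolerant points at low and medium shade tolerance. They
#' approximate the archetypes D5S1, D4S3, D3S4, D2S5, D2S1, D2S3.
#'
#' @return A 6 x 2 matrix with columns `drought_tol`, `shade_tol`.
#' @export
default_centroids <- function() {
  m <- rbind(
    c(2, 1), c(5, 1), c(2, 3), c(4, 3), c(3, 4), c(2, 5)
  )
  colnames(m) <- c("drought_tol", "shade_tol")
  m
}

# Plain Lloyd iteration seeded at the supplied centroids; deterministic,
# ties broken toward the lowest centroid index. Empty clusters keep their
# previous centroid.
.lloyd <- function(x, centroids, max_iter = 100L) {
  k <- nrow(centroids)
  assign_prev <- rep(0L, nrow(x))
  for (it in seq_len(max_iter)) {
    d2 <- outer(rowSums(x^2), rep(1, k)) - 2 * x %*% t(centroids) +
      outer(rep(1, nrow(x)), rowSums(centroids^2))
    assign_new <- max.col(-d2, ties.method = "first")
    if (identical(assign_new, assign_prev)) break
    assign_prev <- assign_new
    for (c in seq_len(k)) {
      sel <- assign_new == c
      if (any(sel)) centroids[c, ] <- colMeans(x[sel, , drop = FALSE])
    }
  }
  list(assignment = assign_prev, centroids = centroids)
}

#' Cluster species into trait groups with seeded k-means
#'
#' Standard Lloyd k-means on the scaled (drought, shade) coordinates,
#' started exactly at the supplied centroids and run to convergence.
#' Deterministic given its inputs.
#'
#' @param scaled Output of [scale_traits()].
#' @param centroids k x 2 matrix of initial centroids on the original 1-5
#'   scale (columns drought, shade); default [default_centroids()]. They are
#'   mapped into the scaled space with the table's scaling parameters.
#' @return List with `traits` (table plus integer `cluster` column),
#'   `centroids` (final, scaled space) and `assignment`.
#' @export
assign_trait_groups <- function(scaled, centroids = default_centroids()) {
  sc <- attr(scaled, "scaling")
  if (is.null(sc)) stop("`scaled` must come from scale_traits()")
  if (anyDuplicated(centroids)) stop("initial centroids must be distinct")
  cen_z <- cbind(
    (centroids[, 1] - sc$drought_tol$center) / sc$drought_tol$scale,
    (centroids[, 2] - sc$shade_tol$center) / sc$shade_tol$scale
  )
  x <- as.matrix(scaled[, c("drought_z", "shade_z")])
  fit <- .lloyd(x, cen_z)
  if (length(unique(fit$assignment)) < nrow(centroids)) {
    warning("k-means converged with one or more empty clusters")
  }
  scaled$cluster <- fit$assignment
  list(traits = scaled, centroids = fit$centroids, assignment = fit$assignment)
}

#' Label trait groups as D<d>S<s>
#'
#' Each cluster is labeled by the rounded mean drought and shade tolerance
#' of its members on the original 1-5 scale (e.g. `D2S5`). Clusters whose
#' codes collide are disambiguated with suffixes `a`, `b`, ...
#'
#' @param grouped Output of [assign_trait_groups()].
#' @return The trait table with a `group` label column; empty clusters get
#'   no rows.
#' @export
label_groups <- function(grouped) {
  tr <- grouped$traits
  ks <- sort(unique(tr$cluster))
  lab <- vapply(ks, function(c) {
    sel <- tr$cluster == c
    sprintf("D%dS%d", round(mean(tr$drought_tol[sel])),
            round(mean(tr$shade_tol[sel])))
  }, character(1))
  dup <- lab[duplicated(lab)]
  for (d in unique(dup)) {
    ix <- which(lab == d)
    lab[ix] <- paste0(d, letters[seq_along(ix)])
  }
  tr$group <- lab[match(tr$cluster, ks)]
  tr
}

#' Build labeled trait groups from a raw trait table
#'
#' Convenience pipeline: [genus_fallback()], [scale_traits()],
#' [assign_trait_groups()], [label_groups()].
#'
#' @inheritParams genus_fallback
#' @inheritParams assign_trait_groups
#' @return Trait table with `drought_z`, `shade_z`, `cluster`, `group`.
#' @export
build_trait_groups <- function(traits, centroids = default_centroids()) {
  label_groups(assign_trait_groups(scale_traits(genus_fallback(traits)),
                                   centroids))
}
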