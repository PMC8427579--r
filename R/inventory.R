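#' Assemble an inventory data set from tree and plot tables
#'
#' Bundles repeated tree lists with plot metadata and derives the census
#' pairs (consecutive census ids per plot) whose date differences define the
#' period lengths used as model offsets.
#'
#' @param trees Data frame `plot_id, census_id, census_date, tree_id,
#'   species, dbh_cm`. `tree_id` must be stable across censuses within a
#'   plot; `dbh_cm > 0`.
#' @param plots Data frame `plot_id, plot_area_ha` with `plot_area_ha > 0`.
#' @param dbh_threshold Native calipering threshold of the inventory (cm).
#' @return An object of class `inventory_data`.
#' @export
inventory_data <- function(trees, plots, dbh_threshold) {
  need_t <- c("plot_id", "census_id", "census_date", "tree_id", "species", "dbh_cm")
  stopifnot(all(need_t %in% names(trees)),
            all(c("plot_id", "plot_area_ha") %in% names(plots)))
  if (dbh_threshold <= 0) stop("`dbh_threshold` must be > 0")
  if (any(trees$dbh_cm <= 0)) stop("all `dbh_cm` must be > 0")
  if (any(plots$plot_area_ha <= 0)) stop("all `plot_area_ha` must be > 0")
  key <- paste(trees$plot_id, trees$census_id, trees$tree_id)
  if (anyDuplicated(key)) stop("duplicate (plot_id, census_id, tree_id) records")
  trees$census_date <- as.Date(trees$census_date)

  pairs <- do.call(rbind, lapply(split(trees, trees$plot_id), function(tr) {
    cen <- unique(tr[, c("census_id", "census_date")])
    cen <- cen[order(cen$census_id), , drop = FALSE]
    if (nrow(cen) < 2L) return(NULL)
    data.frame(
      plot_id = tr$plot_id[1],
      census_1 = cen$census_id[-nrow(cen)],
      census_2 = cen$census_id[-1],
      date_1 = cen$census_date[-nrow(cen)],
      date_2 = cen$census_date[-1],
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(pairs) || nrow(pairs) == 0L) {
    stop("no plot has two or more censuses")
  }
  rownames(pairs) <- NULL
  pairs$period_length <- as.numeric(pairs$date_2 - pairs$date_1) / 365.25
  if (any(pairs$period_length <= 0)) stop("census dates must advance between censuses")
  pairs$period_id <- paste0(pairs$plot_id, ":", pairs$census_1, "-", pairs$census_2)
  pairs$plot_area <- plots$plot_area_ha[match(pairs$plot_id, plots$plot_id)]
  if (anyNA(pairs$plot_area)) stop("plots missing from the plot table")

  structure(
    list(trees = trees, plots = plots, pairs = pairs,
         dbh_threshold = dbh_threshold,
         species = sort(unique(trees$species))),
    class = "inventory_data"
  )
}

#' @export
print.inventory_data <- function(x, ...) {
  cat(sprintf(
    "<inventory_data> %d plots, %d census pairs, %d species, DBH threshold %g cm\n",
    nrow(x$plots), nrow(x$pairs), length(x$species), x$dbh_threshold
  ))
  invisible(x)
}

# Recruit identification for one census pair: first exceedance of the
# threshold. Returns the tree_ids of recruits among `trees_2`.
.recruit_ids <- function(trees_1, trees_2, dbh_threshold) {
  above_2 <- trees_2$dbh_cm >= dbh_threshold
  prev <- match(trees_2$tree_id, trees_1$tree_id)
  was_below <- is.na(prev) | trees_1$dbh_cm[prev] < dbh_threshold
  trees_2$tree_id[above_2 & was_below]
}

#' Count recruits per species for one census pair
#'
#' A tree is a recruit when its DBH is at or above the calipering threshold
#' at the second census and it was either absent or below the threshold at
#' the first census. One row per species is returned, including explicit
#' zero counts for every species in `species` (the modeled universe) so the
#' count model sees its zeros.
#'
#' @param pair One row of the `pairs` table of an [inventory_data()] object
#'   (needs `plot_id`, `period_id`, `plot_area`, `period_length`).
#' @param trees_1,trees_2 Tree records of the first/second census of the pair.
#' @param dbh_threshold Calipering threshold (cm), `> 0`.
#' @param species Character vector: species universe for zero rows. Defaults
#'   to the species present in the recruit set.
#' @return Data frame `plot_id, period_id, species, count, plot_area,
#'   period_length`.
#' @export
count_recruits <- function(pair, trees_1, trees_2, dbh_threshold,
                           species = NULL) {
  if (dbh_threshold <= 0) stop("`dbh_threshold` must be > 0")
  rid <- .recruit_ids(trees_1, trees_2, dbh_threshold)
  rec_sp <- trees_2$species[match(rid, trees_2$tree_id)]
  if (is.null(species)) species <- sort(unique(rec_sp))
  counts <- table(factor(rec_sp, levels = species))
  data.frame(
    plot_id = pair$plot_id,
    period_id = pair$period_id,
    species = species,
    count = as.integer(counts),
    plot_area = pair$plot_area,
    period_length = pair$period_length,
    stringsAsFactors = FALSE
  )
}

#' Stand structure of the second census, excluding recruits
#'
#' Basal area (m^2/ha) and stem density (1/ha) over the census-2 trees at or
#' above the threshold that are not recruits of the period: trees already
#' counted as recruitment are not part of the competing stand.
#'
#' @param trees_2 Tree records of the second census.
#' @param recruits Character vector of recruit `tree_id`s to exclude.
#' @param pair Census-pair row (needs `plot_area`).
#' @param dbh_threshold Calipering threshold (cm).
#' @return One-row data frame `basal_area, stem_density, n_trees`.
#' @export
stand_attributes <- function(trees_2, recruits, pair, dbh_threshold) {
  if (pair$plot_area <= 0) stop("`plot_area` must be > 0")
  keep <- trees_2$dbh_cm >= dbh_threshold & !(trees_2$tree_id %in% recruits)
  n <- sum(keep)
  if (n == 0L && nrow(trees_2) > 0L) {
    warning(sprintf("plot %s: all census-2 trees are recruits; stand is empty",
                    pair$plot_id))
  }
  ba <- sum(pi * (trees_2$dbh_cm[keep] / 200)^2) / pair$plot_area
  data.frame(basal_area = ba, stem_density = n / pair$plot_area, n_trees = n)
}

#' Basal-area-weighted plot shade-casting ability
#'
#' Plot SCA is the mean of species shade-casting ability (1-5) weighted by
#' each species' share of stand basal area, over non-recruit trees.
#'
#' @param trees Tree records of the (non-recruit) stand.
#' @param species_sca Named numeric vector mapping species to SCA in `[1, 5]`.
#' @return Scalar SCA, or `NA` for an empty stand.
#' @export
plot_sca <- function(trees, species_sca) {
  if (nrow(trees) == 0L) return(NA_real_)
  missing_sp <- setdiff(unique(trees$species), names(species_sca))
  if (length(missing_sp) > 0L) {
    stop("no shade-casting ability value for species: ",
         paste(missing_sp, collapse = ", "))
  }
  ba <- pi * (trees$dbh_cm / 200)^2
  ba_sp <- tapply(ba, trees$species, sum)
  sum(species_sca[names(ba_sp)] * ba_sp) / sum(ba_sp)
}

#' Tabulate recruitment observations and stand covariates
#'
#' Runs [count_recruits()], [stand_attributes()] and [plot_sca()] for every
#' census pair of an inventory at the requested threshold(s).
#'
#' @param inv An [inventory_data()] object.
#' @param dbh_threshold Threshold for the response (recruit counts); defaults
#'   to the inventory's native threshold.
#' @param explanatory_threshold Threshold for the stand covariates; defaults
#'   to `dbh_threshold`.
#' @param species_sca Optional named SCA vector; when supplied, plot SCA is
#'   added to the stand table.
#' @param species Species universe for explicit zero rows; defaults to all
#'   species in the inventory.
#' @return List with data frames `observations` (`plot_id, period_id,
#'   species, count, plot_area, period_length`) and `stand` (`plot_id,
#'   period_id, basal_area, stem_density, sca`).
#' @export
tabulate_recruitment <- function(inv, dbh_threshold = inv$dbh_threshold,
                                 explanatory_threshold = dbh_threshold,
                                 species_sca = NULL, species = inv$species) {
  stopifnot(inherits(inv, "inventory_data"))
  obs_list <- vector("list", nrow(inv$pairs))
  stand_list <- vector("list", nrow(inv$pairs))
  for (r in seq_len(nrow(inv$pairs))) {
    pair <- inv$pairs[r, , drop = FALSE]
    t1 <- inv$trees[inv$trees$plot_id == pair$plot_id &
                      inv$trees$census_id == pair$census_1, , drop = FALSE]
    t2 <- inv$trees[inv$trees$plot_id == pair$plot_id &
                      inv$trees$census_id == pair$census_2, , drop = FALSE]
    obs_list[[r]] <- count_recruits(pair, t1, t2, dbh_threshold, species)
    rid <- .recruit_ids(t1, t2, explanatory_threshold)
    st <- stand_attributes(t2, rid, pair, explanatory_threshold)
    keep <- t2$dbh_cm >= explanatory_threshold & !(t2$tree_id %in% rid)
    sca <- if (is.null(species_sca)) NA_real_ else {
      plot_sca(t2[keep, , drop = FALSE], species_sca)
    }
    stand_list[[r]] <- data.frame(
      plot_id = pair$plot_id, period_id = pair$period_id,
      basal_area = st$basal_area, stem_density = st$stem_density, sca = sca,
      stringsAsFactors = FALSE
    )
  }
  out <- list(observations = do.call(rbind, obs_list),
              stand = do.call(rbind, stand_list))
  rownames(out$observations) <- rownames(out$stand) <- NULL
  out
}

#' Recompute a data set at an artificially increased DBH threshold
#'
#' Harmonizes inventories with different native calipering thresholds by
#' recomputing the tables as if only trees at or above `new_threshold` had
#' been calipered. Mode `"both"` raises the threshold for the recruit counts
#' and the stand covariates; `"explanatory"` raises it for the covariates
#' only and keeps the response at the native threshold.
#'
#' @param inv An [inventory_data()] object.
#' @param new_threshold New threshold (cm), `>=` the native threshold.
#' @param mode `"both"` (default) or `"explanatory"`.
#' @inheritParams tabulate_recruitment
#' @return Same structure as [tabulate_recruitment()].
#' @export
harmonize_threshold <- function(inv, new_threshold, mode = c("both", "explanatory"),
                                species_sca = NULL, species = inv$species) {
  mode <- match.arg(mode)
  if (new_threshold < inv$dbh_threshold) {
    stop(sprintf("`new_threshold` (%g) is below the native threshold (%g)",
                 new_threshold, inv$dbh_threshold))
  }
  resp_thr <- if (mode == "both") new_threshold else inv$dbh_threshold
  tabulate_recruitment(inv, dbh_threshold = resp_thr,
                       explanatory_threshold = new_threshold,
                       species_sca = species_sca, species = species)
}
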