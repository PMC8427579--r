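# two-census toy plot reused across tests
toy_trees <- function() {
  data.frame(
    plot_id = "p1",
    census_id = rep(c(1L, 2L), c(5, 7)),
    census_date = rep(c("2000-06-01", "2010-06-01"), c(5, 7)),
    tree_id = c("t1", "t2", "t3", "t4", "t5",
                "t1", "t2", "t3", "t5", "t6", "t7", "t8"),
    species = c("A", "A", "B", "B", "C",
                "A", "A", "B", "C", "A", "C", "B"),
    dbh_cm = c(3.9, 4.5, 8.0, 2.0, 3.0,
               4.2, 9.0, 9.5, 3.5, 5.0, 4.0, 2.5),
    stringsAsFactors = FALSE
  )
}

toy_inventory <- function() {
  inventory_data(toy_trees(), data.frame(plot_id = "p1", plot_area_ha = 0.1),
                 dbh_threshold = 4)
}

test_that("count_recruits identifies first threshold exceedance", {
  inv <- toy_inventory()
  pair <- inv$pairs[1, ]
  t1 <- toy_trees()[1:5, ]; t2 <- toy_trees()[6:12, ]
  obs <- count_recruits(pair, t1, t2, 4, species = c("A", "B", "C"))
  # t1: 3.9 -> 4.2 counted; t2: 4.5 -> 9.0 already above 4, not counted;
  # t6 (A, 5.0) new, counted; t7 (C, 4.0) new, counted; t8 below threshold;
  # t4 died; t5 stays below.
  expect_equal(obs$count[obs$species == "A"], 2L)  # t1 + t6
  expect_equal(obs$count[obs$species == "B"], 0L)
  expect_equal(obs$count[obs$species == "C"], 1L)  # t7
  expect_equal(obs$period_length, rep(10, 3), tolerance = 0.01)
  expect_error(count_recruits(pair, t1, t2, 0), "threshold")
})

test_that("per-species counts match exhaustive enumeration on random plots", {
  set.seed(42)
  for (rep in 1:5) {
    n1 <- sample(5:15, 1); n2 <- sample(5:15, 1)
    ids1 <- sample(sprintf("t%02d", 1:20), n1)
    ids2 <- sample(sprintf("t%02d", 1:20), n2)
    t1 <- data.frame(plot_id = "p", census_id = 1L, census_date = "2000-01-01",
                     tree_id = ids1, species = sample(c("A", "B", "C"), n1, TRUE),
                     dbh_cm = runif(n1, 1, 12))
    t2 <- data.frame(plot_id = "p", census_id = 2L, census_date = "2010-01-01",
                     tree_id = ids2, species = sample(c("A", "B", "C"), n2, TRUE),
                     dbh_cm = runif(n2, 1, 12))
    pair <- data.frame(plot_id = "p", period_id = "p:1-2", plot_area = 0.05,
                       period_length = 10)
    obs <- count_recruits(pair, t1, t2, 7, species = c("A", "B", "C"))
    # brute force over every census-2 tree
    manual <- c(A = 0L, B = 0L, C = 0L)
    for (r in seq_len(n2)) {
      prev <- t1$dbh_cm[t1$tree_id == t2$tree_id[r]]
      if (t2$dbh_cm[r] >= 7 && (length(prev) == 0 || prev < 7)) {
        manual[t2$species[r]] <- manual[t2$species[r]] + 1L
      }
    }
    expect_equal(setNames(obs$count, obs$species), manual)
  }
})

test_that("stand attributes exclude recruits and match hand sums", {
  pair <- data.frame(plot_id = "p", plot_area = 0.02)
  t2 <- data.frame(plot_id = "p", census_id = 2L, census_date = "2010-01-01",
                   tree_id = "x1", species = "A", dbh_cm = 20)
  st <- stand_attributes(t2, character(0), pair, 4)
  expect_equal(st$basal_area, pi * 0.1^2 / 0.02, tolerance = 1e-12)
  expect_equal(st$stem_density, 50)
  # all trees recruits -> empty stand with a warning
  expect_warning(st0 <- stand_attributes(t2, "x1", pair, 4), "recruits")
  expect_equal(c(st0$basal_area, st0$stem_density), c(0, 0))
  # random stand vs independent summation
  set.seed(9)
  t2 <- data.frame(plot_id = "p", census_id = 2L, census_date = "2010-01-01",
                   tree_id = sprintf("x%d", 1:10), species = "A",
                   dbh_cm = runif(10, 2, 40))
  rec <- c("x2", "x5")
  st <- stand_attributes(t2, rec, pair, 6)
  keep <- t2$dbh_cm >= 6 & !t2$tree_id %in% rec
  expect_equal(st$basal_area, sum(pi * (t2$dbh_cm[keep] / 200)^2) / 0.02)
  expect_equal(st$stem_density, sum(keep) / 0.02)
  # additivity over disjoint subsets (before division by area)
  st_a <- stand_attributes(t2[1:5, ], rec, pair, 6)
  st_b <- stand_attributes(t2[6:10, ], rec, pair, 6)
  expect_equal(st_a$basal_area + st_b$basal_area, st$basal_area)
})

test_that("plot SCA is the basal-area-weighted mean", {
  # species A: SCA 5, BA 10; species B: SCA 1, BA 30 -> (50 + 30)/40 = 2
  dbh_for_ba <- function(ba_m2) 200 * sqrt(ba_m2 / pi)
  trees <- data.frame(plot_id = "p", census_id = 2L, census_date = "2010-01-01",
                      tree_id = c("a", "b"), species = c("A", "B"),
                      dbh_cm = dbh_for_ba(c(10, 30)))
  expect_equal(plot_sca(trees, c(A = 5, B = 1)), 2.0)
  expect_equal(plot_sca(trees[1, ], c(A = 4)), 4.0)
  expect_error(plot_sca(trees, c(A = 5)), "B")
  # three-species oracle + bounds
  set.seed(2)
  trees <- data.frame(plot_id = "p", census_id = 2L, census_date = "2010-01-01",
                      tree_id = sprintf("t%d", 1:9),
                      species = rep(c("A", "B", "C"), 3),
                      dbh_cm = runif(9, 5, 50))
  sca <- c(A = 1.5, B = 3, C = 4.5)
  ba <- tapply(pi * (trees$dbh_cm / 200)^2, trees$species, sum)
  expect_equal(plot_sca(trees, sca), sum(sca[names(ba)] * ba) / sum(ba))
  expect_true(plot_sca(trees, sca) >= min(sca) && plot_sca(trees, sca) <= max(sca))
})

test_that("tabulate_recruitment + harmonize_threshold behave as a pipeline", {
  inv <- toy_inventory()
  base <- tabulate_recruitment(inv, species_sca = c(A = 4, B = 2, C = 3))
  expect_equal(nrow(base$observations), 3)  # explicit zeros for all species
  expect_true(all(base$observations$species == c("A", "B", "C")))
  # identity: harmonizing at the native threshold is byte-identical
  expect_identical(harmonize_threshold(inv, 4,
                                       species_sca = c(A = 4, B = 2, C = 3)),
                   base)
  expect_error(harmonize_threshold(inv, 3), "below the native")
  # raising to 8 cm equals a full re-run at 8 cm
  h8 <- harmonize_threshold(inv, 8)
  rerun <- tabulate_recruitment(inv, dbh_threshold = 8)
  expect_identical(h8, rerun)
  # t2 (4.5 -> 9.0) first exceeds 8 cm between the censuses; t3 was
  # already at 8.0 and is not a first exceedance
  expect_equal(setNames(h8$observations$count, h8$observations$species),
               c(A = 1L, B = 0L, C = 0L))
  # explanatory-only mode keeps the native response
  hx <- harmonize_threshold(inv, 8, mode = "explanatory")
  expect_equal(hx$observations$count,
               base$observations$count)
  expect_false(isTRUE(all.equal(hx$stand$basal_area, base$stand$basal_area)))
})

test_that("recruits at a higher threshold respect the dbh bound", {
  set.seed(31)
  syn <- generate_tree_lists(generator_config(n_plots = 6, n_species = 5,
                                              seed = 11))
  inv <- inventory_data(syn$trees, syn$plots, dbh_threshold = 4)
  for (thr in c(4, 12)) {
    tab <- tabulate_recruitment(inv, dbh_threshold = thr)
    for (r in seq_len(nrow(inv$pairs))) {
      pair <- inv$pairs[r, ]
      t1 <- inv$trees[inv$trees$plot_id == pair$plot_id & inv$trees$census_id == pair$census_1, ]
      t2 <- inv$trees[inv$trees$plot_id == pair$plot_id & inv$trees$census_id == pair$census_2, ]
      rid <- ingrowth:::.recruit_ids(t1, t2, thr)
      expect_true(all(t2$dbh_cm[t2$tree_id %in% rid] >= thr))
    }
  }
})
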