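test_that("PhyD greedy rule keeps documented marker sets", {
  map <- make_map(1 + 0:999 * 1000)
  expect_equal(length(prune_phyd(map, 0)), 1000)        # identity threshold
  sel <- prune_phyd(map, 10000)
  expect_equal(length(sel), 100)                         # every 10th marker
  expect_true(all(diff(map$position_bp[sel$indices]) >= 10000))

  sel2 <- prune_phyd(make_map(c(100, 150, 300)), 100)
  expect_identical(sel2$indices, c(1L, 3L))
})

test_that("PhyD always keeps the first marker of every chromosome", {
  map <- rbind(make_map(c(10, 20, 30), 1, "a"), make_map(c(5, 6, 7), 2, "b"))
  sel <- prune_phyd(map, 1e6)
  expect_identical(sel$indices, c(1L, 4L))
})

test_that("GenD removes exactly one of a perfect-LD pair and keeps independent markers", {
  set.seed(21)
  x <- sample(0:2, 200, replace = TRUE, prob = c(0.25, 0.5, 0.25))
  z <- sample(0:2, 200, replace = TRUE, prob = c(0.25, 0.5, 0.25))
  ds <- make_dataset(cbind(x, x, z, z), positions = c(1000, 2000, 10000, 11000))
  sel <- prune_gend(ds, 0.5)
  expect_equal(length(sel), 2)
  expect_equal(sum(sel$indices %in% 1:2), 1)
  expect_equal(sum(sel$indices %in% 3:4), 1)

  ds_ind <- random_dataset(300, 20, seed = 22)            # adjacent r2 ~ 1/n
  expect_equal(length(prune_gend(ds_ind, 0.5)), 20)
})

test_that("three mutually perfect-LD markers in one window leave one survivor", {
  set.seed(23)
  x <- sample(0:2, 150, replace = TRUE, prob = c(0.25, 0.5, 0.25))
  ds <- make_dataset(cbind(x, x, x), positions = c(1000, 2000, 3000))
  sel <- prune_gend(ds, 0.9)
  expect_equal(length(sel), 1)
})

test_that("GenD output passes a full window rescan and rejects bad window geometry", {
  ds <- sim_dataset(n = 120, m = 300, lambda = 2e4, seed = 31,
                    chrom_bp = 6e6)
  sel <- prune_gend(ds, 0.2)
  viol <- panelprune:::gend_violations(ds, sel$indices, 0.2)
  expect_equal(nrow(viol), 0)
  expect_error(prune_gend(ds, 0.2, window_kb = 2, step_kb = 5),
               "window smaller than step")
})

test_that("RanD samples uniformly without replacement", {
  map <- make_map(c(100, 200, 300, 400))
  expect_identical(prune_rand(map, 4, seed = 1)$indices, 1:4)
  expect_identical(prune_rand(map, 2, seed = 9)$indices,
                   prune_rand(map, 2, seed = 9)$indices)
  expect_error(prune_rand(map, 5), "out of range")

  counts <- table(vapply(1:2000, function(s) prune_rand(map, 1, s)$indices,
                         integer(1)))
  expect_true(all(counts >= 500 - 75 & counts <= 500 + 75))
})

test_that("prune_to_count hits exact panel sizes by threshold bisection", {
  ds <- make_dataset(matrix(rep(c(0L, 1L, 2L, 1L, 0L, 2L), 1000), nrow = 6),
                     positions = 1 + 0:999 * 1000)
  sel <- prune_to_count(ds, "PhyD", 100, seed = 1)
  expect_equal(length(sel), 100)
  expect_gte(sel$threshold, 9000)                        # near 10x spacing
  expect_lte(sel$threshold, 10000)
  expect_true(all(diff(ds$map$position_bp[sel$indices]) >= sel$threshold))

  expect_equal(prune_to_count(ds, "PhyD", 1000, seed = 1)$threshold, 0)
})

test_that("GenD target above the perfect-LD ceiling raises 'target unreachable'", {
  set.seed(41)
  x <- sample(0:2, 100, replace = TRUE, prob = c(0.25, 0.5, 0.25))
  z <- sample(0:2, 100, replace = TRUE, prob = c(0.3, 0.5, 0.2))
  ds <- make_dataset(cbind(x, x, z, z), positions = c(1000, 2000, 10000, 11000))
  expect_error(prune_to_count(ds, "GenD", 4, seed = 1), "target unreachable")
  sel <- prune_to_count(ds, "GenD", 2, seed = 1)
  expect_equal(length(sel), 2)
})

test_that("the rank-gap walk reproduces its deterministic arithmetic", {
  sel <- scenario_gap_sample(335753, mean_gap = 67, gap_variance = 0)
  expect_equal(length(sel), floor((335753 - 1) / 67) + 1)  # 5012
  expect_true(all(diff(sel$indices) == 67))
  expect_identical(scenario_gap_sample(100, 1, 0)$indices, 1:100)
  expect_error(scenario_gap_sample(50, 67, 0), "mean_gap")
})

test_that("the stochastic rank-gap walk matches its mean and orders its variance", {
  realized <- function(v, s) {
    idx <- scenario_gap_sample(100000, 67, v, seed = s)$indices
    g <- diff(idx)
    c(mean(g), var(g))
  }
  stats20 <- vapply(1:50, function(s) realized(20, s), numeric(2))
  stats40 <- vapply(1:50, function(s) realized(40, s), numeric(2))
  stats80 <- vapply(1:50, function(s) realized(80, s), numeric(2))
  expect_gte(mean(stats80[1, ]), 65)
  expect_lte(mean(stats80[1, ]), 69)
  expect_lt(mean(stats20[2, ]), mean(stats40[2, ]))
  expect_lt(mean(stats40[2, ]), mean(stats80[2, ]))
})

test_that("all pruning outputs are sorted unique subsets and deterministic", {
  ds <- sim_dataset(n = 60, m = 400, seed = 51, chrom_bp = rep(4e6, 2))
  sels <- list(prune_phyd(ds$map, 15000),
               prune_gend(ds, 0.4),
               prune_rand(ds$map, 120, seed = 2),
               prune_to_count(ds, "PhyD", 150, seed = 3),
               scenario_gap_sample(400, 10, 20, seed = 4))
  for (sel in sels) {
    expect_false(is.unsorted(sel$indices, strictly = TRUE))
    expect_true(all(sel$indices >= 1 & sel$indices <= 400))
  }
  expect_identical(prune_to_count(ds, "PhyD", 150, seed = 3)$indices,
                   prune_to_count(ds, "PhyD", 150, seed = 3)$indices)
})
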