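test_that("uniform spacing gives equal gaps; clustered spacing gives variable gaps", {
  cfg_u <- sim_config(n_individuals = 10, n_markers = 100,
                      chromosome_lengths_bp = 1e5,
                      spacing_model = "uniform", seed = 1)
  map_u <- simulate_marker_map(cfg_u)
  gaps <- diff(map_u$position_bp)
  expect_true(all(gaps == gaps[1]))
  expect_equal(var(gaps), 0)
  expect_equal(nrow(map_u), 100)

  cfg_c <- sim_config(n_individuals = 10, n_markers = 100,
                      chromosome_lengths_bp = 1e5,
                      spacing_model = "clustered", seed = 1)
  map_c <- simulate_marker_map(cfg_c)
  expect_gt(var(diff(map_c$position_bp)), 0)
  expect_true(all(diff(map_c$position_bp) > 0))
  expect_equal(nrow(map_c), 100)
})

test_that("marker map generation is deterministic under a fixed seed and respects chromosome capacity", {
  cfg <- sim_config(n_individuals = 10, n_markers = 500,
                    chromosome_lengths_bp = c(2e6, 1e6), seed = 42)
  expect_identical(simulate_marker_map(cfg), simulate_marker_map(cfg))
  cfg_bad <- sim_config(n_individuals = 10, n_markers = 1000,
                        chromosome_lengths_bp = c(400, 300), seed = 1)
  expect_error(simulate_marker_map(cfg_bad), "too short")
})

test_that("adjacent r2 vanishes in the no-LD limit (lambda -> 0)", {
  cfg <- sim_config(n_individuals = 250, n_markers = 1001,
                    chromosome_lengths_bp = 2e6, spacing_model = "uniform",
                    ld_decay_lambda_bp = 1, seed = 2)
  map <- simulate_marker_map(cfg)
  expect_true(all(diff(map$position_bp) >= 1000))
  ds <- simulate_genotypes(map, cfg)
  r2 <- adjacent_r2(ds)
  expect_gte(length(r2), 1000)
  expect_lt(mean(r2), 0.05)
})

test_that("two markers one decay-length apart realize the e^-1 chain correlation", {
  lambda <- 1e4
  map <- make_map(c(1, 1 + lambda))
  cfg <- sim_config(n_individuals = 2500, n_markers = 2,
                    chromosome_lengths_bp = 2 * lambda,
                    ld_decay_lambda_bp = lambda,
                    maf_low = 0.5, maf_high = 0.5, seed = 9)
  ds <- simulate_genotypes(map, cfg)
  # dosage correlation equals the haplotype allele correlation in
  # expectation (two independent haplotypes per individual = 5000
  # haplotypes); allele relabeling can only flip its sign
  r <- abs(cor(ds$dosages[, 1], ds$dosages[, 2]))
  expect_lt(abs(r - exp(-1)), 0.05)
})

test_that("genotype simulation is deterministic and respects frequency bounds", {
  cfg <- sim_config(n_individuals = 150, n_markers = 400,
                    chromosome_lengths_bp = rep(2e6, 2),
                    maf_low = 0.1, maf_high = 0.4, seed = 5)
  map <- simulate_marker_map(cfg)
  ds1 <- simulate_genotypes(map, cfg)
  ds2 <- simulate_genotypes(map, cfg)
  expect_identical(ds1$dosages, ds2$dosages)
  p <- colMeans(ds1$dosages) / 2
  maf <- pmin(p, 1 - p)
  expect_true(all(maf >= 0.1 - 0.1 & maf <= 0.4 + 0.1))
})

test_that("adjacent r2 decreases with gap size when averaged in bins", {
  ds <- sim_dataset(n = 200, m = 2500, lambda = 5e4, seed = 3,
                    chrom_bp = rep(5e7, 2))
  r2 <- adjacent_r2(ds)
  gaps <- adjacent_gaps(ds$map)
  stopifnot(length(r2) == length(gaps))  # no monomorphic skips expected here
  bins <- cut(gaps, breaks = quantile(gaps, 0:4 / 4), include.lowest = TRUE)
  means <- tapply(r2, bins, mean)
  expect_true(all(table(bins) >= 500))
  expect_true(all(diff(means) <= 0))
})

test_that("a noise-free trait (h2 = 1) equals its breeding values", {
  ds <- random_dataset(80, 60, seed = 4)
  arch <- trait_architecture("SCS_like", h2 = 1, n_small = 40)
  tr <- simulate_trait(ds, arch, seed = 1)
  expect_equal(cor(tr$phenotypes$SCS_like, tr$true_bv), 1)
})

test_that("realized heritability tracks the target for large n", {
  for (s in 1:5) {
    ds <- sim_dataset(n = 1000, m = 1000, seed = s)
    tr <- simulate_trait(ds, trait_architecture("SCS_like", h2 = 0.3),
                         seed = s + 50)
    h2_real <- var(tr$true_bv) / var(tr$phenotypes$SCS_like)
    expect_gte(h2_real, 0.25)
    expect_lte(h2_real, 0.35)
  }
})

test_that("a 10x-SD major QTL carries the largest effect in the clear majority of draws", {
  # independent order-statistic simulation puts the true rate near 0.76
  # (1 major N(0, 10) against the max of 300 |N(0, 1)| draws)
  ds <- random_dataset(30, 400, seed = 8)
  arch <- trait_architecture("FP_like", n_major = 1, major_sd = 10,
                             n_moderate = 0, n_small = 300)
  hits <- vapply(1:100, function(s) {
    q <- simulate_trait(ds, arch, seed = s)$qtl
    q$tier[which.max(abs(q$effect))] == "major"
  }, logical(1))
  expect_gte(mean(hits), 0.6)
})

test_that("doubling all effect sizes quadruples the genetic variance", {
  ds <- random_dataset(200, 400, seed = 6)
  a1 <- trait_architecture("MY_like", h2 = 0.4)
  a2 <- trait_architecture("MY_like", h2 = 0.4, major_sd = 20,
                           moderate_sd = 6, small_sd = 2)
  v1 <- var(simulate_trait(ds, a1, seed = 7)$true_bv)
  v2 <- var(simulate_trait(ds, a2, seed = 7)$true_bv)
  expect_equal(v2 / v1, 4, tolerance = 1e-10)
})

test_that("trait simulation is deterministic and errors on impossible QTL counts", {
  ds <- random_dataset(50, 100, seed = 2)
  arch <- trait_architecture("SCS_like", n_small = 60)
  t1 <- simulate_trait(ds, arch, seed = 3)
  t2 <- simulate_trait(ds, arch, seed = 3)
  expect_identical(t1$phenotypes, t2$phenotypes)
  expect_error(simulate_trait(ds, trait_architecture("SCS_like",
                                                     n_small = 200),
                              seed = 1),
               "more QTL")
})
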