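test_that("baseline simulation is reproducible and obeys the divergence limit", {
  p <- sim_params(n_populations = 6, n_loci = 100, baseline_n = 20)
  b1 <- simulate_baseline(p, seed = 5)
  b2 <- simulate_baseline(p, seed = 5)
  expect_identical(unclass(b1$genotypes), unclass(b2$genotypes))
  expect_identical(b1$freqs, b2$freqs)

  # F -> 0: across-population frequency variance collapses
  p0 <- sim_params(n_populations = 12, n_loci = 300, baseline_n = 5, fst = 1e-4)
  b0 <- simulate_baseline(p0, seed = 6)
  expect_lt(mean(apply(b0$freqs, 2, stats::sd)), 0.01)

  expect_error(sim_params(fst = 0), "fst > 0")
})

test_that("noise model matches the aggregate discrepancy rate on a re-genotyping-sized panel", {
  # 161,280 single-locus comparisons at 1.14% error
  set.seed(21)
  g <- genotype_matrix(matrix(sample(0:2, 480 * 336, replace = TRUE), nrow = 480))
  noisy <- apply_noise(g, error_rate = 0.0114, missing_rate = 0)
  n_diff <- sum(unclass(noisy) != unclass(g))
  expect_lt(abs(n_diff - 1839), 5 * sqrt(161280 * 0.0114 * (1 - 0.0114)))

  expect_identical(unclass(apply_noise(g, 0, 0)), unclass(g))
  a <- apply_noise(g, 0.05, 0.1, seed = 3)
  b <- apply_noise(g, 0.05, 0.1, seed = 3)
  expect_identical(unclass(a), unclass(b))
})

test_that("offspring follow Mendelian transmission exactly when error-free", {
  reg <- manual_registry(rbind(m = c(0L, 0L, 2L, 1L),
                               f = c(0L, 2L, 2L, 1L)))
  p <- sim_params(n_loci = 4, error_rate = 0, missing_rate = 0)
  off <- simulate_offspring(reg, p, n_per_cross = 60, sampling_year = 2019)
  m <- unclass(off$genotypes)
  expect_true(all(m[, 1] == 0))   # aa x aa -> aa
  expect_true(all(m[, 2] == 1))   # aa x AA -> Aa
  expect_true(all(m[, 3] == 2))   # AA x AA -> AA
  expect_true(all(m[, 4] %in% 0:2))
  expect_equal(off$truth$age, rep(3L, 60))
})

test_that("offspring cohorts reproduce the parental population's allele spectrum", {
  w <- small_world(seed = 9, n_populations = 1, n_loci = 300,
                   broodstock_size = 60, brood_years = 2016,
                   error_rate = 0, missing_rate = 0)
  reg <- simulate_broodstock(w$params, w$baseline$freqs, n_crosses = 300)
  off <- simulate_offspring(reg, w$params, n_per_cross = 1, sampling_year = 2019)
  off_freq <- colMeans(unclass(off$genotypes)) / 2
  expect_lt(mean(abs(off_freq - w$baseline$freqs[1, ])), 0.05)
  expect_gt(stats::cor(off_freq, w$baseline$freqs[1, ]), 0.95)
})

test_that("broodstock genotyping success matches the nominal proportion", {
  set.seed(31)
  p <- sim_params(n_populations = 10, n_loci = 30, broodstock_size = 17,
                  brood_years = 2013:2016, genotyping_success = 5 / 17)
  b <- simulate_baseline(p)
  reg <- simulate_broodstock(p, b$freqs)
  # 40 population-years of 17 parents each
  expect_lt(abs(mean(reg$parents$genotyped) - 5 / 17),
            3 * sqrt((5 / 17) * (12 / 17) / nrow(reg$parents)))
  expect_true(all(reg$parents$population %in% p$pop_map$population))

  p1 <- sim_params(n_populations = 2, n_loci = 30, genotyping_success = 1)
  reg1 <- simulate_broodstock(p1, simulate_baseline(p1, seed = 1)$freqs)
  expect_true(all(reg1$parents$genotyped))
})

test_that("fishery samples follow the stratum mixture and age constraints", {
  w <- small_world(seed = 13, n_populations = 3, n_loci = 60,
                   brood_years = 2013:2017)
  # degenerate mixture
  fs1 <- simulate_fishery_sample(w$params, w$baseline$freqs, w$registry,
                                 year = 2019,
                                 mixture = c(pop01 = 1, pop02 = 0, pop03 = 0))
  expect_true(all(fs1$truth$population == "pop01"))

  mix <- c(pop01 = 0.7, pop02 = 0.3, pop03 = 0)
  fs2 <- simulate_fishery_sample(
    w$params, w$baseline$freqs, w$registry, year = 2019,
    strata = tibble::tibble(fishery = "sport", month = "8", n = 1000L),
    mixture = mix)
  p_hat <- mean(fs2$truth$population == "pop01")
  expect_lt(abs(p_hat - 0.7), 3 * sqrt(0.7 * 0.3 / 1000))
  expect_true(all(fs2$truth$age %in% 2:6))
  expect_identical(fs2$meta$stratum, rep("sport:8", 1000))
  expect_true(all(fs2$meta$size_class %in% c("legal", "sublegal")))
})

test_that("the genotyped-parent-pair fraction in fisheries matches the tagging rate p^2", {
  set.seed(17)
  p <- sim_params(n_populations = 1, n_loci = 50, broodstock_size = 40,
                  genotyping_success = 0.6, n_cu = 1)
  b <- simulate_baseline(p)
  reg <- simulate_broodstock(p, b$freqs, n_crosses = 200)
  fs <- simulate_fishery_sample(p, b$freqs, reg, year = 2019,
                                strata = tibble::tibble(fishery = "f", month = "7",
                                                        n = 1000L),
                                mixture = c(pop01 = 1))
  genotyped <- reg$parents$genotyped
  names(genotyped) <- reg$parents$parent_id
  both <- genotyped[fs$truth$parent1] & genotyped[fs$truth$parent2]
  expect_lt(abs(mean(both) - 0.6^2), 0.1)
})
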