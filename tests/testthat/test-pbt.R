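test_that("genetic tagging rates and expected identifications follow the closed forms", {
  tr <- tagging_rate(c(0, 1, 5 / 17))
  expect_equal(tr$two_parent_rate, c(0, 1, (5 / 17)^2))
  expect_equal(tr$one_parent_rate, c(0, 1, 1 - (12 / 17)^2))
  expect_equal(round(tr$two_parent_rate[3], 4), 0.0865)
  expect_equal(round(tr$one_parent_rate[3], 4), 0.5017)
  expect_true(all(tr$two_parent_rate <= tr$one_parent_rate))

  ei <- expected_identifications(c(100, 0), tagging_rate(c(0.5, 0.5)))
  expect_equal(ei$expected_two_parent, c(25, 0))
  expect_equal(ei$expected_one_parent, c(75, 0))
})

test_that("age follows directly from the brood year", {
  expect_identical(age_from_broodyear(2019, 2016), 3L)
  expect_identical(age_from_broodyear(2017, 2016), 1L)  # juvenile
  expect_identical(age_from_broodyear(2019, 2013:2017), as.integer(6:2))
})

test_that("simulated families are recovered with high-probability two-parent assignments", {
  w <- small_world(seed = 101, n_populations = 3, n_loci = 250,
                   broodstock_size = 6, brood_years = 2016)
  off <- simulate_offspring(w$registry, w$params, n_per_cross = 2,
                            sampling_year = 2019)
  res <- assign_parentage(off$genotypes, w$registry, 2019, w$freqs,
                          w$params$pop_map)
  expect_true(all(res$class == "two_parent"))
  expect_true(all(res$probability > 0.95))
  tr <- off$truth[match(res$offspring_id, off$truth$individual_id), ]
  expect_identical(res$population, tr$population)
  expect_identical(res$age, tr$age)
  expect_true(all(mapply(setequal,
                         asplit(cbind(res$parent1, res$parent2), 1),
                         asplit(cbind(tr$parent1, tr$parent2), 1))))
})

test_that("offspring of un-genotyped parents stay unassigned", {
  set.seed(103)
  p <- sim_params(n_populations = 2, n_loci = 200, broodstock_size = 6,
                  brood_years = 2016, genotyping_success = 0)
  b <- simulate_baseline(p)
  reg <- simulate_broodstock(p, b$freqs)
  off <- simulate_offspring(reg, p, n_per_cross = 3, sampling_year = 2019)
  freqs <- allele_frequencies(b$genotypes, b$labels)
  res <- assign_parentage(off$genotypes, reg, 2019, freqs, p$pop_map)
  expect_true(all(res$class == "unassigned"))
})

test_that("candidate pairs with identical genotypes split the probability below threshold", {
  set.seed(107)
  truth <- matrix(sample(0:2, 2 * 250, replace = TRUE,
                         prob = c(0.25, 0.5, 0.25)), nrow = 2,
                  dimnames = list(c("m", "f"), NULL))
  # clone each parent: four genotypically identical candidate pairs
  calls <- rbind(truth, truth)
  rownames(calls) <- c("m1", "f1", "m2", "f2")
  reg <- manual_registry(calls)
  p <- sim_params(n_loci = 250, error_rate = 0, missing_rate = 0)
  reg$crosses <- tibble::tibble(cross_id = "x1", parent1 = "m1", parent2 = "f1",
                                population = "popA", brood_year = 2016L)
  off <- simulate_offspring(reg, p, n_per_cross = 5, sampling_year = 2019)
  freqs <- matrix(0.5, 1, 250, dimnames = list("popA", NULL))
  cand <- assign_broodyear(off$genotypes, reg, 2016, freqs,
                           run_config(error_rate = 0))
  expect_true(all(cand$pair_prob < 0.95))
  expect_true(all(abs(cand$pair_prob - 0.25) < 0.05))
  expect_true(all(cand$duo_prob < 0.95))
  res <- accept_assignments(cand, 2019, population_map("popA", "CU1"))
  expect_true(all(res$class == "unassigned"))
})

test_that("the LLR prescreen leaves assignment probabilities unchanged", {
  w <- small_world(seed = 109, n_populations = 2, n_loci = 150,
                   broodstock_size = 5, brood_years = 2016)
  off <- simulate_offspring(w$registry, w$params, n_per_cross = 1,
                            sampling_year = 2019)
  screened <- assign_broodyear(off$genotypes, w$registry, 2016, w$freqs,
                               run_config())
  brute <- assign_broodyear(off$genotypes, w$registry, 2016, w$freqs,
                            run_config(pair_screen_llr = -Inf))
  expect_equal(screened$pair_prob, brute$pair_prob, tolerance = 1e-10)
  expect_identical(screened$pair_parent1, brute$pair_parent1)
})

acceptance_case <- function(pair_prob = NA_real_, duo_prob = NA_real_,
                            brood_year = 2016L, pop = "popA",
                            id = "off1") {
  tibble::tibble(offspring_id = id, brood_year = brood_year,
                 pair_parent1 = ifelse(is.na(pair_prob), NA, "pa"),
                 pair_parent2 = ifelse(is.na(pair_prob), NA, "pb"),
                 pair_population = ifelse(is.na(pair_prob), NA, pop),
                 pair_prob = pair_prob,
                 duo_parent = ifelse(is.na(duo_prob), NA, "pd"),
                 duo_population = ifelse(is.na(duo_prob), NA, pop),
                 duo_prob = duo_prob, n_pairs = 10L, n_duos = 5L)
}

test_that("acceptance rules fire in the documented order", {
  pm <- population_map(c("popA", "popB", "popC"), c("CU1", "CU1", "CU2"))
  gsi_same <- tibble::tibble(individual_id = "off1", population = "popB")
  gsi_other <- tibble::tibble(individual_id = "off1", population = "popC")

  # two-parent threshold
  res <- accept_assignments(acceptance_case(pair_prob = 0.96), 2019, pm)
  expect_identical(res$class, "two_parent")
  expect_identical(res$age, 3L)
  res <- accept_assignments(acceptance_case(pair_prob = 0.94), 2019, pm)
  expect_identical(res$class, "unassigned")

  # two-parent precedence over a strong single in another year
  cand <- dplyr::bind_rows(acceptance_case(pair_prob = 0.97, brood_year = 2016L),
                           acceptance_case(duo_prob = 0.99, brood_year = 2015L))
  res <- accept_assignments(cand, 2019, pm, gsi_same)
  expect_identical(res$class, "two_parent")
  expect_identical(res$brood_year, 2016L)

  # cross-year margin: 0.97 vs 0.93 fails the 0.05 margin
  cand <- dplyr::bind_rows(acceptance_case(duo_prob = 0.97, brood_year = 2016L),
                           acceptance_case(duo_prob = 0.93, brood_year = 2015L))
  expect_identical(accept_assignments(cand, 2019, pm, gsi_same)$class,
                   "unassigned")
  # 0.97 vs 0.91 passes the margin and the CU check
  cand <- dplyr::bind_rows(acceptance_case(duo_prob = 0.97, brood_year = 2016L),
                           acceptance_case(duo_prob = 0.91, brood_year = 2015L))
  res <- accept_assignments(cand, 2019, pm, gsi_same)
  expect_identical(res$class, "one_parent")
  expect_identical(res$brood_year, 2016L)

  # CU discordance rejects; so does a missing GSI posterior
  expect_identical(accept_assignments(cand, 2019, pm, gsi_other)$class,
                   "unassigned")
  expect_identical(accept_assignments(cand, 2019, pm, gsi_map = NULL)$class,
                   "unassigned")

  # candidates implying ages outside 2-6 are ineligible
  res <- accept_assignments(acceptance_case(pair_prob = 0.99, brood_year = 2018L),
                            2019, pm)
  expect_identical(res$class, "unassigned")
  res <- accept_assignments(acceptance_case(pair_prob = 0.99, brood_year = 2018L),
                            2019, pm, ages = 1L)
  expect_identical(res$class, "two_parent")
  expect_identical(res$age, 1L)
})

test_that("removing true parents drives the accepted-assignment rate to zero", {
  w <- small_world(seed = 113, n_populations = 3, n_loci = 250,
                   broodstock_size = 6, brood_years = 2015:2016)
  off <- simulate_offspring(w$registry, w$params, n_per_cross = 2,
                            sampling_year = 2019)
  audit <- false_positive_audit(off$genotypes, w$registry, off$truth, 2019,
                                w$freqs, w$params$pop_map)
  expect_identical(audit$n_accepted, 0L)
  expect_equal(audit$rate, 0)

  # lowering thresholds can only raise the rate
  loose <- false_positive_audit(off$genotypes, w$registry, off$truth, 2019,
                                w$freqs, w$params$pop_map,
                                config = run_config(accept_prob = 0.5,
                                                    single_parent_margin = 0))
  expect_gte(loose$rate, audit$rate)

  # an empty registry cannot assign anything
  empty <- w$registry
  empty$parents$genotyped <- FALSE
  empty$genotypes <- genotype_matrix(
    unclass(w$registry$genotypes)[0, , drop = FALSE],
    locus_ids = colnames(w$registry$genotypes))
  res <- assign_parentage(off$genotypes, empty, 2019, w$freqs, w$params$pop_map)
  expect_true(all(res$class == "unassigned"))
})
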