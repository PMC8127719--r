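test_that("degenerate baselines give degenerate mixtures", {
  g <- genotype_matrix(matrix(sample(0:2, 20 * 30, replace = TRUE), nrow = 20))
  freqs <- matrix(runif(30, 0.2, 0.8), 1, 30, dimnames = list("only", NULL))
  res <- gibbs_mixture(g, freqs, fast_config(), seed = 1)
  expect_true(all(res$theta_draws == 1))
  comp <- summarize_composition(res)
  expect_equal(comp$mean, 1)
  expect_equal(comp$sd, 0)
})

test_that("fixed-difference populations are resolved almost deterministically", {
  set.seed(53)
  L <- 60
  freqs <- rbind(p1 = rep(0.98, L), p2 = rep(0.02, L))
  g <- genotype_matrix(matrix(rbinom(120 * L, 2, 0.98), nrow = 120))  # all p1
  res <- gibbs_mixture(g, freqs, fast_config(), seed = 2)
  comp <- summarize_composition(res)
  expect_gt(comp$mean[comp$population == "p1"], 0.99)
  expect_true(all(abs(rowSums(res$theta_draws) - 1) < 1e-9))
  expect_true(all(abs(rowSums(res$indiv_posterior) - 1) < 1e-9))
})

test_that("a 70/30 mixture is recovered within posterior uncertainty", {
  set.seed(59)
  p <- sim_params(n_populations = 2, n_loci = 300, fst = 0.05, baseline_n = 150)
  b <- simulate_baseline(p)
  freqs <- allele_frequencies(b$genotypes, b$labels)
  origin <- sample(c("pop01", "pop02"), 400, replace = TRUE, prob = c(0.7, 0.3))
  calls <- t(vapply(origin, function(pop)
    rbinom(300, 2, b$freqs[pop, ]), integer(300)))
  rownames(calls) <- sprintf("m%03d", seq_len(400))
  g <- apply_noise(genotype_matrix(calls), p$error_rate, p$missing_rate)
  res <- gibbs_mixture(g, freqs, fast_config(), seed = 3)
  comp <- summarize_composition(res)
  expect_lt(abs(comp$mean[1] - 0.7), 2 * comp$sd[1] + 0.05)
  expect_equal(sum(comp$mean), 1)
})

test_that("composition summaries agree with direct computation over the draws", {
  draws <- matrix(c(0.6, 0.7, 0.5, 0.4, 0.3, 0.5), ncol = 2,
                  dimnames = list(NULL, c("a", "b")))
  res <- structure(list(theta_draws = draws), class = "mixture_result")
  comp <- summarize_composition(res)
  expect_equal(comp$mean, unname(colMeans(draws)))
  expect_equal(comp$sd, unname(apply(draws, 2, sd)))
})

test_that("CU aggregation sums population allocations", {
  pm <- population_map(c("a", "b", "c"), c("CU1", "CU1", "CU2"))
  comp <- tibble::tibble(population = c("a", "b", "c"),
                         mean = c(0.2, 0.3, 0.5))
  agg <- aggregate_to_cu(comp, pm)
  expect_equal(agg$mean[agg$cu == "CU1"], 0.5)
  expect_equal(sum(agg$mean), 1)

  one_cu <- population_map(c("a", "b", "c"), "CU1")
  expect_equal(aggregate_to_cu(comp, one_cu)$mean, 1)

  draws <- matrix(c(0.2, 0.25, 0.3, 0.35, 0.5, 0.4), ncol = 3,
                  dimnames = list(NULL, c("a", "b", "c")))
  aggd <- aggregate_to_cu(draws, pm)
  expect_equal(aggd$mean[aggd$cu == "CU1"], mean(c(0.5, 0.6)))
  expect_equal(aggd$sd[aggd$cu == "CU2"], sd(c(0.5, 0.4)))
})

test_that("permuting the baseline order permutes the estimates (up to Monte-Carlo error)", {
  set.seed(61)
  p <- sim_params(n_populations = 3, n_loci = 150, baseline_n = 80)
  b <- simulate_baseline(p)
  freqs <- allele_frequencies(b$genotypes, b$labels)
  g <- genotype_matrix(t(vapply(rep(c("pop01", "pop02", "pop03"), c(50, 30, 20)),
                                function(pop) rbinom(150, 2, b$freqs[pop, ]),
                                integer(150))),
                       individual_ids = sprintf("x%03d", 1:100))
  res1 <- summarize_composition(gibbs_mixture(g, freqs, fast_config(), seed = 4))
  perm <- c("pop03", "pop01", "pop02")
  res2 <- summarize_composition(gibbs_mixture(g, freqs[perm, ], fast_config(),
                                              seed = 5))
  res2 <- res2[match(res1$population, res2$population), ]
  expect_lt(max(abs(res1$mean - res2$mean)), 4 * max(res1$sd, res2$sd))
})

test_that("posterior intervals are calibrated over simulation replicates", {
  set.seed(67)
  cfg <- run_config(iterations = 1200, burn_in = 300, retained = 300)
  hits <- vapply(seq_len(20), function(rep) {
    p <- sim_params(n_populations = 2, n_loci = 120, baseline_n = 80)
    b <- simulate_baseline(p)
    freqs <- allele_frequencies(b$genotypes, b$labels)
    origin <- sample(c("pop01", "pop02"), 120, replace = TRUE, prob = c(0.6, 0.4))
    calls <- t(vapply(origin, function(pop) rbinom(120, 2, b$freqs[pop, ]),
                      integer(120)))
    rownames(calls) <- sprintf("m%03d", seq_along(origin))
    g <- apply_noise(genotype_matrix(calls), p$error_rate, p$missing_rate)
    res <- gibbs_mixture(g, freqs, cfg)
    ci <- quantile(res$theta_draws[, "pop01"], c(0.025, 0.975))
    ci[1] <= 0.6 && 0.6 <= ci[2]
  }, logical(1))
  expect_gte(sum(hits), 17)
})
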