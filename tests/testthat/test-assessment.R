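test_that("CWT expansions reproduce the worked example and its boundary cases", {
  expect_equal(cwt_estimated(20, 1000, 5000), 100)
  expect_equal(cwt_estimated(20, 1000, 1000), 20)   # fully sampled catch
  expect_equal(cwt_estimated(0, 1000, 5000), 0)
  # tag loss applied before the sampling expansion
  expect_equal(cwt_estimated(18, 1000, 5000, tag_loss = 0.1), 100)
  expect_error(cwt_estimated(5, 2000, 1000), "exceeds")

  exp1 <- cwt_expanded(100, 0.10)
  expect_equal(exp1$expanded, 1000)
  expect_false(exp1$capped)
  expect_equal(cwt_expanded(100, 1)$expanded, 100)
  expect_warning(capped <- cwt_expanded(100, 0.10, total_release = 800), "capped")
  expect_equal(capped$expanded, 800)
  expect_true(capped$capped)
  # linearity below the cap
  expect_equal(cwt_expanded(cwt_estimated(40, 1000, 5000), 0.1)$expanded,
               2 * cwt_expanded(cwt_estimated(20, 1000, 5000), 0.1)$expanded)
})

test_that("catch-by-population conserves the ledger total and pools unsampled months", {
  ledger <- tibble::tibble(fishery = c("troll", "troll", "sport"),
                           month = c("6", "7", "7"),
                           catch = c(1000, 2000, 500))
  comps <- tibble::tibble(
    fishery = rep(c("troll", "troll", "sport"), each = 2),
    month = rep(c("6", "7", "7"), each = 2),
    population = rep(c("a", "b"), 3),
    share = c(0.25, 0.75, 0.5, 0.5, 0.1, 0.9))
  res <- catch_by_population(ledger, comps,
                             population_map(c("a", "b"), c("CU1", "CU2")))
  expect_equal(sum(res$by_population$catch), sum(ledger$catch))
  expect_equal(res$by_population$catch[res$by_population$population == "a"],
               1000 * 0.25 + 2000 * 0.5 + 500 * 0.1)
  expect_equal(res$by_cu$catch, res$by_population$catch)

  # unsampled stratum pools to the nearest sampled month in the fishery
  ledger2 <- tibble::tibble(fishery = "troll", month = "8", catch = 300)
  expect_warning(res2 <- catch_by_population(ledger2, comps), "pooling to month 7")
  expect_equal(res2$by_population$catch, c(150, 150))
})

test_that("shared-broodstock apportionment follows the ratio source", {
  rel <- apportion_shared(1000, c(`Little Qualicum` = 2236140,
                                  `Big Qualicum` = 3403467))
  expect_equal(round(100 * rel$share, 1), c(39.7, 60.3))
  ids <- apportion_shared(1000, c(Chilliwack = 303, Capilano = 131))
  expect_equal(round(100 * ids$share, 1), c(69.8, 30.2))
  expect_equal(apportion_shared(10, c(a = 2, b = 2))$share, c(0.5, 0.5))
  expect_equal(sum(ids$catch), 1000)
  expect_error(apportion_shared(10, c(a = 0, b = 0)), "zero")
})

test_that("age-specific catch needs 20 identifications and conserves the total", {
  expect_message(none <- age_specific_catch(1000, c(`3` = 10, `4` = 9)),
                 "no age split")
  expect_null(none)
  split <- age_specific_catch(1000, c(`3` = 60, `4` = 40))
  expect_equal(split$catch, c(600, 400))
  expect_equal(sum(split$catch), 1000)
})

test_that("exploitation rate is the catch fraction and is monotone", {
  expect_equal(round(exploitation_rate(95067, 37568), 1), 71.7)
  expect_equal(round(exploitation_rate(45, 3858), 1), 1.2)
  expect_equal(exploitation_rate(0, 100), 0)
  expect_gt(exploitation_rate(200, 100), exploitation_rate(100, 100))
  expect_lt(exploitation_rate(100, 200), exploitation_rate(100, 100))
})

test_that("exploitation-rate comparisons use Pearson correlation with exclusions", {
  x <- c(a = 10, b = 20, c = 40, d = 70)
  expect_equal(compare_er(x, x)$r, 1)
  expect_equal(compare_er(x, -x)$r, -1)
  ex <- compare_er(x, c(10, 20, 40, 0), exclude = "d")
  expect_identical(ex$n, 3L)
  expect_equal(ex$r, 1)
  expect_error(compare_er(x[1:2], x[1:2]), "at least 3")
})

test_that("mean ages and age concordance reproduce the published summaries", {
  expect_equal(round(mean_age(c(`2` = 6, `3` = 691, `4` = 141, `5` = 2)), 2), 3.17)
  expect_equal(round(mean_age(c(`2` = 147, `3` = 69, `4` = 1)), 2), 2.33)
  expect_equal(mean_age(c(`4` = 17)), 4)

  tab <- tibble::tibble(cwt_age = c(3, 3, 4), pbt_age = c(3, 4, 4),
                        n = c(90, 10, 100))
  expect_equal(age_concordance(tab), 95)
})

test_that("the wild-escapement ratio estimator and its delta-method SD are correct", {
  expect_equal(escapement_wild(100, 100, 500)$e_ws, 500)
  expect_equal(escapement_wild(200, 100, 100)$e_ws, 200)

  set.seed(73)
  mu1 <- 800; sd1 <- 40; mu2 <- 400; sd2 <- 30; ehs <- 1200
  est <- escapement_wild(mu1, mu2, ehs, sd_c_ws = sd1, sd_c_hs = sd2)
  draws <- ehs * rnorm(2e5, mu1, sd1) / rnorm(2e5, mu2, sd2)
  expect_lt(abs(est$e_ws - mean(draws)) / est$e_ws, 0.01)
  expect_lt(abs(est$sd - sd(draws)) / sd(draws), 0.05)
})

test_that("the cost model reproduces the program cost components", {
  cm <- cost_model(fish_tagged = 6275000, tag_cost = 0.13, handling_cost = 0.14,
                   maintenance = 30000, tags_recovered = 13400,
                   recovery_cost = 5, broodstock_genotyped = 20000,
                   fishery_genotyped = 23000, genotype_cost = 20)
  expect_equal(cm$cwt_marking, 1724250)
  expect_equal(cm$cwt_recovery, 67000)
  expect_equal(cm$pbt_total, 860000)
  expect_equal(cm$differential, cm$cwt_total - cm$pbt_total)

  idle <- cost_model(0, 0.13, 0.14, 30000, 0, 5, 0, 0, 20)
  expect_equal(idle$cwt_total, 30000)
  expect_equal(idle$pbt_total, 0)
})
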