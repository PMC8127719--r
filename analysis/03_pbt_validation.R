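#!/usr/bin/env Rscript
# Step 3 -- validate parentage-based tagging.
#
# Three audits on simulated known-origin fish:
#  (a) assignment accuracy to population and age for the 2019 fishery
#      sample (all broodstock genotyped, so near-complete tagging);
#  (b) observed vs expected identification counts across populations with
#      genotyping success p between 0.3 and 1 (tagging-rate check);
#  (c) the false-positive audit: true parents removed, assignment re-run.

suppressPackageStartupMessages(library(pbtgsi))
if (!file.exists("scratch/world.rds")) stop("run analysis/01_simulate.R first")
world <- readRDS("scratch/world.rds")
set.seed(3001)
cfg <- run_config()

## (a) accuracy at study scale ---------------------------------------------
gsi <- gibbs_mixture(world$fishery$genotypes, world$freqs, cfg, seed = 31)
gmap <- map_population(gsi)
res <- assign_parentage(world$fishery$genotypes, world$registry, 2019,
                        world$freqs, world$params$pop_map, gmap, cfg)
accepted <- res[res$class != "unassigned", ]
truth <- world$fishery$truth[match(accepted$offspring_id,
                                   world$fishery$truth$individual_id), ]
acc_pop <- 100 * mean(accepted$population == truth$population)
acc_age <- 100 * mean(accepted$age == truth$age)
message(sprintf("accepted %d/%d (%.1f%%): population accuracy %.2f%%, age accuracy %.2f%%",
                nrow(accepted), nrow(res),
                identification_rate(nrow(accepted), nrow(res)),
                acc_pop, acc_age))
utils::write.csv(res, "results/pbt_assignments.csv", row.names = FALSE)

## (b) observed vs expected identifications --------------------------------
p_grid <- seq(0.3, 1, by = 0.1)
p_mat <- matrix(p_grid, 8, 2, dimnames = list(sprintf("pop%02d", 1:8), 2015:2016))
params_p <- sim_params(n_populations = 8, n_loci = 389, baseline_n = 60,
                       broodstock_size = 30, brood_years = 2015:2016,
                       genotyping_success = p_mat)
bl_p <- simulate_baseline(params_p)
reg_p <- simulate_broodstock(params_p, bl_p$freqs, n_crosses = 75)
off_p <- simulate_offspring(reg_p, params_p, n_per_cross = 1,
                            sampling_year = 2019)
freqs_p <- allele_frequencies(bl_p$genotypes, bl_p$labels)
res_p <- assign_parentage(off_p$genotypes, reg_p, 2019, freqs_p,
                          params_p$pop_map)
two <- res_p[res_p$class == "two_parent", ]
oe <- do.call(rbind, lapply(seq_len(nrow(reg_p$genotyping_success)), function(i) {
  row <- reg_p$genotyping_success[i, ]
  n <- sum(off_p$truth$population == row$population &
             off_p$truth$brood_year == row$brood_year)
  exp_two <- expected_identifications(
    n, tagging_rate(row$p_realized))$expected_two_parent
  obs_two <- sum(two$population == row$population &
                   two$brood_year == row$brood_year)
  data.frame(population = row$population, brood_year = row$brood_year,
             p = row$p_realized, n = n,
             expected_two_parent = exp_two, observed_two_parent = obs_two)
}))
utils::write.csv(oe, "results/pbt_expected_observed.csv", row.names = FALSE)
fit <- stats::lm(observed_two_parent ~ expected_two_parent, data = oe)
message(sprintf("observed ~ expected two-parent identifications: slope %.3f (ideal 1)",
                stats::coef(fit)[2]))

## (c) false-positive audit -------------------------------------------------
fp <- false_positive_audit(world$fishery$genotypes, world$registry,
                           world$fishery$truth, 2019, world$freqs,
                           world$params$pop_map, gmap, cfg)
message(sprintf("false-positive audit: %d accepted of %d offspring (%.2f%%)",
                fp$n_accepted, fp$n_offspring, 100 * fp$rate))

summary_tab <- data.frame(
  metric = c("accepted", "identification_rate_pct", "accuracy_population_pct",
             "accuracy_age_pct", "obs_vs_exp_slope", "false_positive_pct"),
  value = c(nrow(accepted), identification_rate(nrow(accepted), nrow(res)),
            acc_pop, acc_age, unname(stats::coef(fit)[2]), 100 * fp$rate))
utils::write.csv(summary_tab, "results/pbt_validation_summary.csv",
                 row.names = FALSE)
saveRDS(list(assignments = res, gsi = gsi, gmap = gmap),
        "scratch/pbt_results.rds")
message("summaries written to results/pbt_validation_summary.csv")
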