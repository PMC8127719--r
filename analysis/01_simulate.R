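#!/usr/bin/env Rscript
# Step 1 -- build the synthetic study system.
#
# Generates the desk-scale rendering of the coastwide assessment program:
# a 16-population x 389-SNP baseline diverged at F = 0.05, hatchery
# broodstocks for brood years 2013-2017 with full genotyping, and a
# 1500-fish mixed-stock 2019 fishery sample with ages 2-6, 1.14% per-locus
# genotyping error and 2% missing calls. The simulated world is cached
# under scratch/ for the later steps; small summaries go to results/.

suppressPackageStartupMessages(library(pbtgsi))
dir.create("scratch", showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)
set.seed(20190801)

params <- sim_params()
message("simulating baseline: ", params$n_populations, " populations x ",
        params$n_loci, " SNPs, ", params$baseline_n, " fish each")
baseline <- simulate_baseline(params)

message("simulating broodstocks for brood years ",
        paste(range(params$brood_years), collapse = "-"))
registry <- simulate_broodstock(params, baseline$freqs)

message("simulating the 2019 mixed-stock fishery sample (n = 1500)")
fishery <- simulate_fishery_sample(
  params, baseline$freqs, registry, year = 2019,
  strata = tibble::tibble(fishery = "mixed", month = "7", n = 1500L))

# QC: the 150-locus retention filter (everything passes at 2% missingness,
# but the gate is part of the pipeline)
fishery$genotypes <- qc_min_loci(fishery$genotypes, 150)

world <- list(params = params, baseline = baseline, registry = registry,
              fishery = fishery,
              freqs = allele_frequencies(baseline$genotypes, baseline$labels))
saveRDS(world, "scratch/world.rds")

# interchange copies of the simulated tables (core_io format)
write_genotypes(fishery$genotypes, "scratch/fishery_genotypes.tsv")
utils::write.csv(fishery$truth, "scratch/fishery_truth.csv", row.names = FALSE)

summary_tab <- data.frame(
  population = params$populations,
  cu = world$params$pop_map$cu,
  baseline_n = params$baseline_n,
  mean_freq = rowMeans(baseline$freqs),
  broodstock_per_year = params$broodstock_size)
utils::write.csv(summary_tab, "results/simulated_baseline_summary.csv",
                 row.names = FALSE)
message("world cached in scratch/world.rds; summary in results/simulated_baseline_summary.csv")
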