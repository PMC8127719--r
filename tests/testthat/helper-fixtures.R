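# Shared in-code fixtures: small simulated worlds used across test files.

fast_config <- function(...) {
  run_config(iterations = 2000, burn_in = 500, retained = 500, ...)
}

# A small but informative world: enough loci that true families are
# unambiguous, small enough to simulate in well under a second.
small_world <- function(seed = 42, n_populations = 4, n_loci = 200,
                        baseline_n = 60, broodstock_size = 8,
                        brood_years = 2015:2016, ...) {
  set.seed(seed)
  params <- sim_params(n_populations = n_populations, n_loci = n_loci,
                       baseline_n = baseline_n,
                       broodstock_size = broodstock_size,
                       brood_years = brood_years, ...)
  baseline <- simulate_baseline(params)
  registry <- simulate_broodstock(params, baseline$freqs)
  freqs <- allele_frequencies(baseline$genotypes, baseline$labels)
  list(params = params, baseline = baseline, registry = registry,
       freqs = freqs)
}

# Hand-built registry around explicit true parental genotypes, for exact
# Mendelian checks.
manual_registry <- function(true_calls, population = "popA",
                            brood_year = 2016L, genotyped = TRUE,
                            observed = NULL) {
  gm <- genotype_matrix(true_calls)
  ids <- rownames(gm)
  genotyped <- rep_len(genotyped, length(ids))
  crosses <- tibble::tibble(cross_id = "x1", parent1 = ids[1], parent2 = ids[2],
                            population = population, brood_year = brood_year)
  obs <- if (is.null(observed)) {
    genotype_matrix(unclass(gm)[genotyped, , drop = FALSE],
                    locus_ids = colnames(gm))
  } else observed
  list(parents = tibble::tibble(parent_id = ids, population = population,
                                brood_year = brood_year, genotyped = genotyped),
       genotypes = obs, true_genotypes = gm, crosses = crosses,
       populations = population, brood_years = brood_year)
}
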