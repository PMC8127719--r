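#' Analysis configuration
#'
#' Bundles the tunable parameters shared across the PBT and GSI stages.
#' Defaults follow the operational settings of the Chinook salmon
#' genetics-based assessment program: a 1.14% per-locus genotyping error
#' rate, retention of individuals genotyped at 150+ SNPs, a 25,000-iteration
#' MCMC with 5,000 burn-in of which the last 5,000 draws are retained, a
#' 0.95 assignment-probability threshold, a 0.05 margin for competing
#' cross-year single-parent assignments, ages 2-6 for fishery samples, and
#' a 20-identification minimum before PBT age ratios are used to apportion
#' catch.
#'
#' @param error_rate per-locus genotyping error rate epsilon in `[0, 1)`.
#' @param min_loci minimum non-missing calls for an individual to be retained.
#' @param iterations,burn_in,retained MCMC schedule; the retained draws are
#'   the last `retained` iterations and must fit after burn-in.
#' @param accept_prob assignment probability threshold for accepting a
#'   parentage assignment.
#' @param single_parent_margin minimum probability margin between competing
#'   single-parent assignments in alternate brood years.
#' @param min_age_count minimum PBT identifications before age ratios are
#'   applied to a population's catch.
#' @param ages inclusive age range admissible for fishery samples.
#' @param min_shared_loci minimum loci called in both offspring and
#'   candidate(s) for a comparison to be evaluated.
#' @param likelihood_floor per-locus probability floor applied to trio/duo
#'   tables when `error_rate` is exactly 0, so a single bad call cannot
#'   zero a true family; ignored when `error_rate > 0` (the error model
#'   absorbs miscalls).
#' @param pair_screen_llr single-parent log-likelihood-ratio threshold a
#'   candidate must exceed before parent pairs involving it are evaluated.
#'   A true parent of a panel-scale offspring scores far above 0 while an
#'   unrelated fish scores far below, so the default 0 prunes pairs whose
#'   likelihood contribution is numerically negligible; set `-Inf` to
#'   evaluate every pair.
#' @param unrelated_prior prior mass on the unrelated hypothesis when
#'   normalizing candidate likelihoods; the complement is spread uniformly
#'   over candidates. Use `1 - p^2` when a single broodstock genotyping
#'   proportion `p` applies.
#' @param pseudocount Dirichlet pseudocount added per allele when
#'   estimating baseline frequencies.
#' @param seed optional integer seed recorded for the run.
#' @return a list of class `"run_config"`.
#' @export
run_config <- function(error_rate = 0.0114,
                       min_loci = 150,
                       iterations = 25000,
                       burn_in = 5000,
                       retained = 5000,
                       accept_prob = 0.95,
                       single_parent_margin = 0.05,
                       min_age_count = 20,
                       ages = c(2L, 6L),
                       min_shared_loci = 100,
                       pair_screen_llr = 0,
                       likelihood_floor = 1e-9,
                       unrelated_prior = 0.5,
                       pseudocount = 0.5,
                       seed = NULL) {
  stopifnot(error_rate >= 0, error_rate < 1,
            accept_prob > 0, accept_prob <= 1,
            single_parent_margin >= 0, single_parent_margin <= 1,
            unrelated_prior > 0, unrelated_prior < 1,
            min_loci >= 0, min_shared_loci >= 0,
            pseudocount >= 0, iterations >= 1,
            burn_in >= 0, retained >= 1)
  if (retained > iterations - burn_in) {
    stop("'retained' must not exceed iterations - burn_in")
  }
  structure(list(error_rate = error_rate, min_loci = min_loci,
                 iterations = iterations, burn_in = burn_in,
                 retained = retained, accept_prob = accept_prob,
                 single_parent_margin = single_parent_margin,
                 min_age_count = min_age_count,
                 ages = as.integer(ages),
                 min_shared_loci = min_shared_loci,
                 pair_screen_llr = pair_screen_llr,
                 likelihood_floor = likelihood_floor,
                 unrelated_prior = unrelated_prior,
                 pseudocount = pseudocount, seed = seed),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  }
  invisible(x)
}

#' Population to conservation-unit map
#'
#' A total mapping from baseline population to conservation unit (CU) and
#' from CU to reporting region. CUs are the reporting-group level at which
#' stock compositions and fishery impacts are summarized under the Wild
#' Salmon Policy.
#'
#' @param population character vector of population names (unique).
#' @param cu CU label per population (non-empty).
#' @param region optional region label per population; defaults to the CU.
#' @return a tibble with columns `population`, `cu`, `region`.
#' @export
population_map <- function(population, cu, region = cu) {
  population <- as.character(population)
  cu <- rep_len(as.character(cu), length(population))
  region <- rep_len(as.character(region), length(population))
  if (anyDuplicated(population)) stop("duplicate population names")
  if (any(!nzchar(cu))) stop("CU labels must be non-empty")
  cu_region <- unique(data.frame(cu = cu, region = region))
  if (anyDuplicated(cu_region$cu)) stop("each CU must map to a single region")
  tibble::tibble(population = population, cu = cu, region = region)
}

#' Look up the CU of each population, erroring on gaps
#' @noRd
cu_of <- function(populations, pop_map) {
  idx <- match(populations, pop_map$population)
  if (anyNA(idx)) {
    stop("population(s) missing from the population map: ",
         paste(unique(populations[is.na(idx)]), collapse = ", "))
  }
  pop_map$cu[idx]
}
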