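#' Genetic tagging rates
#'
#' With a proportion `p` of a population-year's broodstock successfully
#' genotyped, a random offspring of that broodstock has both parents
#' genotyped with probability `p^2` (two-parent tagging rate) and at least
#' one parent genotyped with probability `1 - (1 - p)^2` (one-parent rate).
#'
#' @param p proportion of broodstock successfully genotyped (vectorized).
#' @return tibble with columns `p`, `two_parent_rate`, `one_parent_rate`.
#' @export
tagging_rate <- function(p) {
  stopifnot(all(p >= 0), all(p <= 1))
  tibble::tibble(p = p, two_parent_rate = p^2,
                 one_parent_rate = 1 - (1 - p)^2)
}

#' Expected number of PBT identifications
#'
#' Sample size times genetic tagging rate, for two-parent and one-parent
#' assignments.
#'
#' @param sample_size number of genotyped individuals from the population.
#' @param rates a row (or rows) from [tagging_rate()].
#' @return tibble with `expected_two_parent` and `expected_one_parent`.
#' @export
expected_identifications <- function(sample_size, rates) {
  stopifnot(all(sample_size >= 0))
  tibble::tibble(sample_size = sample_size,
                 expected_two_parent = sample_size * rates$two_parent_rate,
                 expected_one_parent = sample_size * rates$one_parent_rate)
}

#' Age implied by a brood-year assignment
#'
#' Once parents are identified in a hatchery broodstock, the fish's age is
#' the difference between the fishery (or broodstock) sampling year and the
#' brood year in which its parents were spawned.
#'
#' @param sample_year calendar year of sampling.
#' @param brood_year calendar year of the parental broodstock.
#' @return integer age(s).
#' @export
age_from_broodyear <- function(sample_year, brood_year) {
  as.integer(sample_year - brood_year)
}

# Marginal (baseline-average) log-probability of each observed offspring
# genotype: the unrelated hypothesis. freqs are pseudocount-smoothed.
unrelated_log_table <- function(freqs, error_rate) {
  obs <- hw_obs_prob(freqs, error_rate)           # list of K x L
  sapply(obs, function(pk) log(colMeans(pk)))     # L x 3
}

# Posterior probability of each candidate against the unrelated hypothesis
# under a flat prior over candidates: prior mass w on unrelated, (1 - w)/J
# per candidate. llr holds log-likelihood ratios vs unrelated (rows =
# offspring). Returns a matrix of posterior probabilities.
candidate_posterior <- function(llr, w) {
  J <- ncol(llr)
  post <- matrix(NA_real_, nrow(llr), J)
  for (i in seq_len(nrow(llr))) {
    x <- llr[i, ]
    ok <- !is.na(x)
    if (!any(ok)) next
    lmax <- max(x[ok], 0)
    num <- (1 - w) / J * exp(x - lmax)
    denom <- sum(num[ok]) + w * exp(-lmax)
    post[i, ] <- num / denom
  }
  post
}

#' Score offspring against all candidate parents of one brood year
#'
#' Evaluates every offspring against every eligible candidate parent pair
#' (both parents genotyped, same population, same brood year) and every
#' single genotyped parent of the brood year, under the trio and duo
#' likelihoods with the configured genotyping-error rate. Likelihoods are
#' converted to assignment probabilities by normalizing over the candidate
#' set plus an unrelated hypothesis whose genotype probabilities come from
#' the baseline allele frequencies; each comparison uses only loci called
#' in all genotypes involved (pairwise deletion), with a minimum
#' shared-locus requirement.
#'
#' @param offspring a [genotype_matrix()] of individuals to assign.
#' @param registry broodstock registry (see [simulate_broodstock()] for the
#'   structure: `parents` tibble plus observed `genotypes`).
#' @param brood_year the single brood year to score against.
#' @param baseline_freqs pseudocount-smoothed K x L population frequency
#'   matrix (loci aligned with `offspring`); used for the unrelated
#'   hypothesis and the duo likelihood's untyped mate.
#' @param config a [run_config()].
#' @return tibble with one row per offspring: the best-supported parent
#'   pair and single parent for this brood year with their assignment
#'   probabilities (`NA` where no eligible candidate exists).
#' @export
assign_broodyear <- function(offspring, registry, brood_year, baseline_freqs,
                             config = run_config()) {
  par_tab <- registry$parents
  par_tab <- par_tab[par_tab$brood_year == brood_year & par_tab$genotyped, ,
                     drop = FALSE]
  n_off <- nrow(offspring)
  out <- tibble::tibble(
    offspring_id = rownames(offspring), brood_year = brood_year,
    pair_parent1 = NA_character_, pair_parent2 = NA_character_,
    pair_population = NA_character_, pair_prob = NA_real_,
    duo_parent = NA_character_, duo_population = NA_character_,
    duo_prob = NA_real_, n_pairs = 0L, n_duos = 0L)
  if (nrow(par_tab) == 0L) return(out)

  eps <- config$error_rate
  floor_p <- if (eps == 0) config$likelihood_floor else 0
  parG <- unclass(registry$genotypes)[par_tab$parent_id, , drop = FALSE]
  offT <- t(drop_gm(offspring))
  parT <- t(parG)
  storage.mode(parT) <- "integer"
  logU <- unrelated_log_table(baseline_freqs, eps)

  # single-parent candidates: every genotyped parent, untyped mate
  # integrated out at the candidate population's frequencies
  duo_llr <- matrix(NA_real_, n_off, nrow(par_tab))
  for (pop in unique(par_tab$population)) {
    idx <- which(par_tab$population == pop)
    dt <- duo_table(baseline_freqs[pop, ], eps)
    if (floor_p > 0) dt <- pmax(dt, floor_p)
    sc <- duo_parent_scores_cpp(offT, parT, idx - 1L, log(dt), logU,
                                as.integer(config$min_shared_loci))
    duo_llr[, idx] <- sc$llr
  }
  post <- candidate_posterior(duo_llr, config$unrelated_prior)
  best <- apply(post, 1L, function(x) if (all(is.na(x))) NA_integer_ else which.max(x))
  sel <- !is.na(best)
  out$duo_parent[sel] <- par_tab$parent_id[best[sel]]
  out$duo_population[sel] <- par_tab$population[best[sel]]
  out$duo_prob[sel] <- post[cbind(which(sel), best[sel])]
  out$n_duos <- nrow(par_tab)

  # candidate pairs: all unordered pairs of genotyped parents within a
  # population-year (two-parent assignments are only eligible when both
  # parents share population and brood year). Pairs are scored only where
  # both members pass the single-parent LLR screen; everything else
  # contributes a numerically negligible likelihood.
  pair_list <- lapply(split(seq_len(nrow(par_tab)), par_tab$population),
                      function(idx) {
                        if (length(idx) < 2) return(NULL)
                        t(utils::combn(idx, 2))
                      })
  pair_idx <- do.call(rbind, pair_list)
  if (!is.null(pair_idx) && nrow(pair_idx)) {
    tt <- trio_table(eps)
    if (floor_p > 0) tt <- pmax(tt, floor_p)
    logT <- log(as.vector(tt))
    keep <- !is.na(duo_llr) & duo_llr > config$pair_screen_llr
    if (!is.finite(config$pair_screen_llr)) keep[] <- TRUE
    sc <- trio_pair_scores_cpp(offT, parT,
                               pair_idx[, 1] - 1L, pair_idx[, 2] - 1L,
                               logT, logU, as.integer(config$min_shared_loci),
                               keep)
    post <- candidate_posterior(sc$llr, config$unrelated_prior)
    best <- apply(post, 1L, function(x) if (all(is.na(x))) NA_integer_ else which.max(x))
    sel <- !is.na(best)
    out$pair_parent1[sel] <- par_tab$parent_id[pair_idx[best[sel], 1]]
    out$pair_parent2[sel] <- par_tab$parent_id[pair_idx[best[sel], 2]]
    out$pair_population[sel] <- par_tab$population[pair_idx[best[sel], 1]]
    out$pair_prob[sel] <- post[cbind(which(sel), best[sel])]
    out$n_pairs <- nrow(pair_idx)
  }
  out
}

#' Apply the acceptance rules to per-broodyear candidates
#'
#' Resolves each offspring's candidates across brood years into at most one
#' accepted parentage record, applying the acceptance rules in order:
#'
#' 1. A two-parent assignment (both parents same population and brood
#'    year) is accepted when its probability meets the threshold; it takes
#'    precedence, and single-parent assignments in alternate years are
#'    then rejected.
#' 2. Among single-parent assignments in competing brood years, the
#'    highest-probability one is accepted only if it meets the threshold
#'    and exceeds the runner-up by at least the configured margin.
#' 3. A surviving single-parent assignment is accepted only if the GSI
#'    maximum-posterior population for the individual lies in the same
#'    conservation unit as the PBT population; individuals lacking a GSI
#'    posterior have the candidate rejected.
#'
#' Candidates whose implied age falls outside the admissible range are
#' ineligible. Unresolved offspring are returned as `unassigned` and are
#' the ones passed to GSI-only treatment downstream.
#'
#' @param candidates row-bound output of [assign_broodyear()] over the
#'   brood years considered.
#' @param sample_year sampling year, fixing age = sample_year - brood year.
#' @param pop_map a [population_map()] covering all candidate and GSI
#'   populations.
#' @param gsi_map optional tibble (`individual_id`, `population`) of GSI
#'   maximum-posterior populations, required to accept single-parent
#'   assignments.
#' @param config a [run_config()].
#' @param ages admissible integer ages; defaults to the range in `config`.
#' @return tibble with one row per offspring: `offspring_id`, `class`
#'   (`two_parent`, `one_parent` or `unassigned`), `parent1`, `parent2`,
#'   `population`, `brood_year`, `age`, `probability`.
#' @export
accept_assignments <- function(candidates, sample_year, pop_map,
                               gsi_map = NULL, config = run_config(),
                               ages = NULL) {
  if (is.null(ages)) ages <- seq(config$ages[1], config$ages[2])
  cand <- candidates
  cand$age <- age_from_broodyear(sample_year, cand$brood_year)
  cand <- cand[cand$age %in% ages, , drop = FALSE]
  gsi_pop <- if (is.null(gsi_map)) character(0) else
    stats::setNames(gsi_map$population, gsi_map$individual_id)

  resolve_one <- function(rows) {
    id <- rows$offspring_id[1]
    unassigned <- tibble::tibble(
      offspring_id = id, class = "unassigned", parent1 = NA_character_,
      parent2 = NA_character_, population = NA_character_,
      brood_year = NA_integer_, age = NA_integer_, probability = NA_real_)
    # rule 1: two-parent precedence
    two <- rows[!is.na(rows$pair_prob) & rows$pair_prob >= config$accept_prob, ]
    if (nrow(two)) {
      b <- two[which.max(two$pair_prob), ]
      return(tibble::tibble(offspring_id = id, class = "two_parent",
                            parent1 = b$pair_parent1, parent2 = b$pair_parent2,
                            population = b$pair_population,
                            brood_year = b$brood_year, age = b$age,
                            probability = b$pair_prob))
    }
    # rule 2: competing single-parent assignments across brood years
    one <- rows[!is.na(rows$duo_prob), ]
    if (!nrow(one)) return(unassigned)
    one <- one[order(-one$duo_prob), ]
    b <- one[1, ]
    if (b$duo_prob < config$accept_prob) return(unassigned)
    if (nrow(one) >= 2 &&
        b$duo_prob - one$duo_prob[2] < config$single_parent_margin) {
      return(unassigned)
    }
    # rule 3: CU concordance with the GSI assignment
    gsi <- gsi_pop[id]
    if (is.na(gsi)) return(unassigned)
    if (cu_of(gsi, pop_map) != cu_of(b$duo_population, pop_map)) {
      return(unassigned)
    }
    tibble::tibble(offspring_id = id, class = "one_parent",
                   parent1 = b$duo_parent, parent2 = NA_character_,
                   population = b$duo_population, brood_year = b$brood_year,
                   age = b$age, probability = b$duo_prob)
  }

  ids <- unique(candidates$offspring_id)
  split_rows <- split(cand, factor(cand$offspring_id, levels = ids))
  dplyr::bind_rows(lapply(split_rows, function(rows) {
    if (nrow(rows) == 0) {
      tibble::tibble(offspring_id = NA_character_, class = "unassigned",
                     parent1 = NA_character_, parent2 = NA_character_,
                     population = NA_character_, brood_year = NA_integer_,
                     age = NA_integer_, probability = NA_real_)
    } else resolve_one(rows)
  }), .id = NULL) -> res
  # offspring whose candidates were all age-filtered away still get a row
  res$offspring_id[is.na(res$offspring_id)] <-
    setdiff(ids, res$offspring_id[!is.na(res$offspring_id)])
  res
}

#' Run per-broodyear scoring and acceptance over a set of brood years
#'
#' Convenience pipeline step: scores offspring against each brood year in
#' turn and applies the acceptance rules.
#'
#' @inheritParams assign_broodyear
#' @inheritParams accept_assignments
#' @param brood_years brood years to score; defaults to all in the registry.
#' @return as [accept_assignments()].
#' @export
assign_parentage <- function(offspring, registry, sample_year, baseline_freqs,
                             pop_map, gsi_map = NULL, config = run_config(),
                             brood_years = NULL, ages = NULL) {
  if (is.null(brood_years)) brood_years <- registry$brood_years
  cands <- dplyr::bind_rows(lapply(brood_years, function(by) {
    assign_broodyear(offspring, registry, by, baseline_freqs, config)
  }))
  accept_assignments(cands, sample_year, pop_map, gsi_map, config, ages)
}

#' False-positive audit by parent removal
#'
#' Removes each offspring's true parents from the registry, re-runs the
#' full assignment, and reports the proportion of offspring that still
#' receive an accepted assignment --- all of which are false positives,
#' since the true parents are no longer available. On well-separated
#' baselines at the default acceptance thresholds the expected rate is 0.
#'
#' @param offspring a [genotype_matrix()].
#' @param registry broodstock registry.
#' @param truth truth tibble with `parent1`, `parent2` per offspring.
#' @inheritParams assign_parentage
#' @return list with `rate` (accepted / offspring), `n_accepted`,
#'   `n_offspring` and the `assignments` table.
#' @export
false_positive_audit <- function(offspring, registry, truth, sample_year,
                                 baseline_freqs, pop_map, gsi_map = NULL,
                                 config = run_config(), brood_years = NULL,
                                 ages = NULL) {
  true_parents <- stats::na.omit(unique(c(truth$parent1, truth$parent2)))
  registry2 <- registry
  registry2$parents <- registry$parents[
    !registry$parents$parent_id %in% true_parents, , drop = FALSE]
  keep <- setdiff(rownames(registry$genotypes), true_parents)
  registry2$genotypes <- genotype_matrix(
    unclass(registry$genotypes)[keep, , drop = FALSE],
    locus_ids = colnames(registry$genotypes))
  res <- assign_parentage(offspring, registry2, sample_year, baseline_freqs,
                          pop_map, gsi_map, config, brood_years, ages)
  n_acc <- sum(res$class != "unassigned")
  list(rate = n_acc / nrow(offspring), n_accepted = n_acc,
       n_offspring = nrow(offspring), assignments = res)
}
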