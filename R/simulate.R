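#' Simulation parameters
#'
#' Describes the statistical structure emulated by the synthetic-data
#' generator: a multi-population SNP baseline with Balding-Nichols
#' divergence around shared ancestral frequencies, hatchery broodstocks
#' sampled over a run of brood years with incomplete genotyping, polygamous
#' within-population mating, Mendelian offspring of ages 2-6 entering
#' mixed-stock fishery samples, and symmetric genotyping error plus random
#' missingness on every observed genotype. Defaults are a desk-scale
#' rendering of an operational coastwide program (hundreds of populations,
#' 389 usable SNPs): 16 populations x 389 loci, 100 baseline fish per
#' population, five brood years, divergence F = 0.05, error rate 1.14%.
#'
#' @param n_populations number of baseline populations.
#' @param n_loci number of biallelic SNPs.
#' @param fst Balding-Nichols divergence parameter F in (0, 1). When
#'   `fst_within_cu` is supplied, `fst` acts at the CU level and
#'   `fst_within_cu` adds population divergence within CU (two-level
#'   hierarchy).
#' @param fst_within_cu optional within-CU divergence for the hierarchical
#'   variant; `NULL` (default) draws all populations independently.
#' @param baseline_n baseline sample size per population.
#' @param brood_years integer vector of broodstock sampling years.
#' @param broodstock_size candidate parents per population per brood year.
#' @param genotyping_success proportion `p` of broodstock successfully
#'   genotyped; scalar, or a `population x brood_year` matrix.
#' @param error_rate per-locus genotyping error rate applied to every
#'   observed genotype.
#' @param missing_rate per-call missing probability.
#' @param age_dist named probability vector over offspring ages 2-6 in
#'   fishery samples.
#' @param sublegal_prob named vector: probability an individual of each age
#'   is below the legal size limit.
#' @param n_cu number of conservation units the populations are grouped
#'   into (contiguous blocks).
#' @param ancestral_range range of the uniform draw for ancestral allele
#'   frequencies.
#' @return list of class `"sim_params"`.
#' @export
sim_params <- function(n_populations = 16,
                       n_loci = 389,
                       fst = 0.05,
                       fst_within_cu = NULL,
                       baseline_n = 100,
                       brood_years = 2013:2017,
                       broodstock_size = 16,
                       genotyping_success = 1,
                       error_rate = 0.0114,
                       missing_rate = 0.02,
                       age_dist = c(`2` = 0.15, `3` = 0.45, `4` = 0.30,
                                    `5` = 0.07, `6` = 0.03),
                       sublegal_prob = c(`2` = 0.85, `3` = 0.30, `4` = 0.02,
                                         `5` = 0, `6` = 0),
                       n_cu = max(1L, n_populations %/% 2L),
                       ancestral_range = c(0.1, 0.9)) {
  stopifnot(fst > 0, fst < 1, n_populations >= 1, n_loci >= 1,
            error_rate >= 0, error_rate < 1,
            missing_rate >= 0, missing_rate < 1,
            abs(sum(age_dist) - 1) < 1e-8,
            all(names(age_dist) %in% as.character(2:6)))
  if (!is.null(fst_within_cu)) stopifnot(fst_within_cu > 0, fst_within_cu < 1)
  populations <- sprintf("pop%02d", seq_len(n_populations))
  cu <- sprintf("CU%02d", rep(seq_len(n_cu), length.out = n_populations,
                              each = ceiling(n_populations / n_cu)))
  structure(list(n_populations = n_populations, n_loci = n_loci,
                 fst = fst, fst_within_cu = fst_within_cu,
                 baseline_n = baseline_n,
                 brood_years = as.integer(brood_years),
                 broodstock_size = broodstock_size,
                 genotyping_success = genotyping_success,
                 error_rate = error_rate, missing_rate = missing_rate,
                 age_dist = age_dist, sublegal_prob = sublegal_prob,
                 populations = populations,
                 pop_map = population_map(populations, cu[seq_len(n_populations)]),
                 ancestral_range = ancestral_range),
            class = "sim_params")
}

# Balding-Nichols draw: Beta with mean p and "coancestry" parameter F.
rbalding_nichols <- function(n, p, f) {
  a <- p * (1 - f) / f
  b <- (1 - p) * (1 - f) / f
  stats::rbeta(n, a, b)
}

# Hardy-Weinberg genotypes: n individuals at L loci with ref-allele
# frequencies freq (length L). Returns n x L integer matrix.
rhw_genotypes <- function(n, freq) {
  L <- length(freq)
  matrix(stats::rbinom(n * L, 2L, rep(freq, each = n)), nrow = n)
}

#' Simulate a multi-population SNP baseline
#'
#' Draws ancestral allele frequencies uniformly, per-population frequencies
#' from a Balding-Nichols (beta) distribution with divergence `fst` (or a
#' two-level CU/population hierarchy when `fst_within_cu` is set), and
#' baseline genotypes in Hardy-Weinberg proportions within population.
#' Genotyping noise and missingness are applied via [apply_noise()].
#'
#' @param params a [sim_params()] object.
#' @param seed optional seed for reproducibility.
#' @return list with `freqs` (true K x L frequency matrix), `genotypes`
#'   (observed baseline [genotype_matrix()]), `labels` (population of each
#'   baseline individual) and `pop_map`.
#' @export
simulate_baseline <- function(params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  K <- params$n_populations
  L <- params$n_loci
  anc <- stats::runif(L, params$ancestral_range[1], params$ancestral_range[2])
  freqs <- matrix(0, K, L, dimnames = list(params$populations, sprintf("L%03d", seq_len(L))))
  if (is.null(params$fst_within_cu)) {
    for (k in seq_len(K)) freqs[k, ] <- rbalding_nichols(L, anc, params$fst)
  } else {
    cus <- unique(params$pop_map$cu)
    cu_freq <- matrix(0, length(cus), L, dimnames = list(cus, NULL))
    for (j in seq_along(cus)) cu_freq[j, ] <- rbalding_nichols(L, anc, params$fst)
    for (k in seq_len(K)) {
      freqs[k, ] <- rbalding_nichols(L, cu_freq[params$pop_map$cu[k], ],
                                     params$fst_within_cu)
    }
  }
  n <- params$baseline_n
  labels <- rep(params$populations, each = n)
  calls <- matrix(NA_integer_, K * n, L)
  for (k in seq_len(K)) {
    calls[(k - 1) * n + seq_len(n), ] <- rhw_genotypes(n, freqs[k, ])
  }
  g <- genotype_matrix(calls,
                       individual_ids = sprintf("%s_b%03d", labels,
                                                rep(seq_len(n), times = K)),
                       locus_ids = colnames(freqs))
  g <- apply_noise(g, params$error_rate, params$missing_rate)
  list(freqs = freqs, genotypes = g,
       labels = stats::setNames(labels, rownames(g)),
       pop_map = params$pop_map)
}

#' Apply genotyping noise to a genotype matrix
#'
#' Each non-missing call is independently replaced, with probability
#' `error_rate`, by one of the other two genotype codes (chosen uniformly),
#' and independently set to missing with probability `missing_rate` --- the
#' same symmetric error model assumed by the parentage and GSI likelihoods.
#'
#' @param g a [genotype_matrix()] of true genotypes.
#' @param error_rate per-call error probability.
#' @param missing_rate per-call missing probability.
#' @param seed optional seed.
#' @return a [genotype_matrix()] of observed genotypes.
#' @export
apply_noise <- function(g, error_rate, missing_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- drop_gm(g)
  ncall <- length(m)
  if (error_rate > 0) {
    flip <- !is.na(m) & stats::runif(ncall) < error_rate
    if (any(flip)) {
      # uniform over the two wrong codes: shift by 1 or 2 mod 3
      m[flip] <- (m[flip] + sample(1:2, sum(flip), replace = TRUE)) %% 3L
    }
  }
  if (missing_rate > 0) {
    m[stats::runif(ncall) < missing_rate] <- NA_integer_
  }
  genotype_matrix(m, rownames(g), colnames(g))
}

#' Simulate hatchery broodstocks over brood years
#'
#' For each population and brood year, draws candidate parents from the
#' population's allele frequencies, marks each as successfully genotyped
#' with probability `p` (the broodstock genotyping-success proportion), and
#' forms polygamous matings by randomly pairing parents within the
#' population-year. Observed genotypes of the genotyped parents carry the
#' usual noise; true genotypes of all parents are kept as ground truth.
#'
#' @param params a [sim_params()] object.
#' @param freqs true population frequency matrix from [simulate_baseline()].
#' @param n_crosses matings per population-year; defaults to the broodstock
#'   size (parents appear in several crosses).
#' @param seed optional seed.
#' @return a broodstock registry: list with `parents` (tibble: parent_id,
#'   population, brood_year, genotyped), `genotypes` (observed
#'   [genotype_matrix()] of genotyped parents), `true_genotypes` (all
#'   parents), `crosses` (tibble: cross_id, parent1, parent2, population,
#'   brood_year) and `genotyping_success` (realized and nominal `p` per
#'   population-year).
#' @export
simulate_broodstock <- function(params, freqs, n_crosses = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_crosses)) n_crosses <- params$broodstock_size
  pops <- params$populations
  years <- params$brood_years
  p_mat <- params$genotyping_success
  if (is.null(dim(p_mat))) {
    p_mat <- matrix(p_mat, length(pops), length(years),
                    dimnames = list(pops, years))
  }
  parents <- list(); cross_rows <- list(); success_rows <- list()
  true_calls <- list()
  for (pop in pops) for (iy in seq_along(years)) {
    yr <- years[iy]
    n_par <- params$broodstock_size
    ids <- sprintf("%s_%d_P%02d", pop, yr, seq_len(n_par))
    gt <- rhw_genotypes(n_par, freqs[pop, ])
    rownames(gt) <- ids
    genotyped <- stats::runif(n_par) < p_mat[pop, as.character(yr)]
    parents[[paste(pop, yr)]] <- tibble::tibble(
      parent_id = ids, population = pop, brood_year = yr, genotyped = genotyped)
    true_calls[[paste(pop, yr)]] <- gt
    # polygamous matings among the population-year's parents
    p1 <- sample(ids, n_crosses, replace = TRUE)
    p2 <- vapply(p1, function(a) sample(setdiff(ids, a), 1L), character(1))
    cross_rows[[paste(pop, yr)]] <- tibble::tibble(
      cross_id = sprintf("%s_%d_X%02d", pop, yr, seq_len(n_crosses)),
      parent1 = p1, parent2 = unname(p2), population = pop, brood_year = yr)
    success_rows[[paste(pop, yr)]] <- tibble::tibble(
      population = pop, brood_year = yr,
      p_nominal = unname(p_mat[pop, as.character(yr)]),
      p_realized = mean(genotyped), n_parents = n_par)
  }
  parents <- dplyr::bind_rows(parents)
  crosses <- dplyr::bind_rows(cross_rows)
  success <- dplyr::bind_rows(success_rows)
  true_genotypes <- genotype_matrix(do.call(rbind, true_calls),
                                    locus_ids = colnames(freqs))
  obs <- unclass(true_genotypes)[parents$parent_id[parents$genotyped], , drop = FALSE]
  obs <- apply_noise(genotype_matrix(obs, locus_ids = colnames(freqs)),
                     params$error_rate, params$missing_rate)
  list(parents = parents, genotypes = obs, true_genotypes = true_genotypes,
       crosses = crosses, genotyping_success = success,
       populations = pops, brood_years = years)
}

# Mendelian offspring from true parental genotype matrices (rows align).
mendelian_cross <- function(gm, gf) {
  stopifnot(all(dim(gm) == dim(gf)))
  a1 <- matrix(stats::rbinom(length(gm), 1L, gm / 2), nrow = nrow(gm))
  a2 <- matrix(stats::rbinom(length(gf), 1L, gf / 2), nrow = nrow(gf))
  a1 + a2
}

#' Simulate known-origin offspring from broodstock crosses
#'
#' Generates offspring by Mendelian transmission from the true genotypes of
#' each registered cross, then applies genotyping noise. These play the
#' role of known-age juvenile or coded-wire-tagged validation samples.
#'
#' @param registry broodstock registry from [simulate_broodstock()].
#' @param params the [sim_params()] used to build the registry.
#' @param n_per_cross offspring per cross.
#' @param sampling_year calendar year the offspring are sampled (fixes true
#'   age as `sampling_year - brood_year`).
#' @param brood_years restrict to these brood years (default: all).
#' @param seed optional seed.
#' @return list with `genotypes` (observed [genotype_matrix()]) and `truth`
#'   (tibble: individual_id, population, parent1, parent2, brood_year, age).
#' @export
simulate_offspring <- function(registry, params, n_per_cross = 1,
                               sampling_year, brood_years = NULL,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  crosses <- registry$crosses
  if (!is.null(brood_years)) {
    crosses <- crosses[crosses$brood_year %in% brood_years, , drop = FALSE]
  }
  idx <- rep(seq_len(nrow(crosses)), each = n_per_cross)
  gm <- unclass(registry$true_genotypes)[crosses$parent1[idx], , drop = FALSE]
  gf <- unclass(registry$true_genotypes)[crosses$parent2[idx], , drop = FALSE]
  calls <- mendelian_cross(gm, gf)
  ids <- sprintf("off_%05d", seq_len(nrow(calls)))
  g <- genotype_matrix(calls, individual_ids = ids,
                       locus_ids = colnames(registry$true_genotypes))
  g <- apply_noise(g, params$error_rate, params$missing_rate)
  truth <- tibble::tibble(individual_id = ids,
                          population = crosses$population[idx],
                          parent1 = crosses$parent1[idx],
                          parent2 = crosses$parent2[idx],
                          brood_year = crosses$brood_year[idx],
                          age = as.integer(sampling_year - crosses$brood_year[idx]))
  list(genotypes = g, truth = truth)
}

#' Simulate a mixed-stock fishery sample
#'
#' Draws individual origins from per-stratum mixture proportions over the
#' baseline populations. Individuals from populations present in the
#' broodstock registry are hatchery-origin: an age is drawn from the age
#' distribution (restricted to ages whose brood year is in the registry),
#' and the individual is generated by Mendelian transmission from a random
#' cross of that population and brood year --- so the fraction of
#' hatchery-origin fish with both parents genotyped matches the two-parent
#' genetic tagging rate p-squared. Other populations contribute wild fish
#' drawn from their allele frequencies.
#'
#' @param params a [sim_params()] object.
#' @param freqs true frequency matrix from [simulate_baseline()].
#' @param registry broodstock registry from [simulate_broodstock()].
#' @param year fishery sampling year.
#' @param strata tibble with columns `fishery`, `month`, `n`; defaults to a
#'   single 500-fish stratum.
#' @param mixture named proportions over populations (recycled across
#'   strata), or a `strata x populations` matrix; rows must sum to 1.
#' @param seed optional seed.
#' @return list with `genotypes`, `meta` (tibble: individual_id,
#'   collection_year, fishery, month, stratum, size_class) and `truth`
#'   (tibble with true population, parents, brood year, age; `NA` parents
#'   for wild fish).
#' @export
simulate_fishery_sample <- function(params, freqs, registry, year,
                                    strata = NULL, mixture = NULL,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pops <- params$populations
  if (is.null(strata)) {
    strata <- tibble::tibble(fishery = "fishery1", month = "Jul", n = 500L)
  }
  if (is.null(mixture)) {
    mixture <- stats::setNames(rep(1 / length(pops), length(pops)), pops)
  }
  mix <- if (is.null(dim(mixture))) {
    matrix(mixture[pops], nrow(strata), length(pops), byrow = TRUE,
           dimnames = list(NULL, pops))
  } else mixture[, pops, drop = FALSE]
  mix[is.na(mix)] <- 0
  if (any(abs(rowSums(mix) - 1) > 1e-6)) stop("mixture proportions must sum to 1 per stratum")

  ages_avail <- sort(as.integer(names(params$age_dist)))
  hatchery_pops <- intersect(pops, registry$populations)
  rows_meta <- list(); rows_truth <- list(); calls_list <- list()
  counter <- 0L
  for (s in seq_len(nrow(strata))) {
    n <- strata$n[s]
    origin <- sample(pops, n, replace = TRUE, prob = mix[s, ])
    age <- sample(ages_avail, n, replace = TRUE,
                  prob = params$age_dist[as.character(ages_avail)])
    ids <- sprintf("fish_%06d", counter + seq_len(n))
    counter <- counter + n
    calls <- matrix(NA_integer_, n, params$n_loci)
    parent1 <- parent2 <- rep(NA_character_, n)
    brood_year <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      pop <- origin[i]
      by <- year - age[i]
      hatchery <- pop %in% hatchery_pops && by %in% registry$brood_years
      if (hatchery) {
        cand <- which(registry$crosses$population == pop &
                        registry$crosses$brood_year == by)
        cx <- cand[sample.int(length(cand), 1L)]
        p1 <- registry$crosses$parent1[cx]
        p2 <- registry$crosses$parent2[cx]
        gm <- unclass(registry$true_genotypes)[p1, , drop = FALSE]
        gf <- unclass(registry$true_genotypes)[p2, , drop = FALSE]
        calls[i, ] <- mendelian_cross(gm, gf)
        parent1[i] <- p1; parent2[i] <- p2; brood_year[i] <- by
      } else {
        calls[i, ] <- rhw_genotypes(1L, freqs[pop, ])
      }
    }
    sub_p <- params$sublegal_prob[as.character(age)]
    sub_p[is.na(sub_p)] <- 0
    size_class <- ifelse(stats::runif(n) < sub_p, "sublegal", "legal")
    rows_meta[[s]] <- tibble::tibble(
      individual_id = ids, collection_year = year,
      fishery = strata$fishery[s], month = strata$month[s],
      stratum = paste(strata$fishery[s], strata$month[s], sep = ":"),
      size_class = size_class)
    rows_truth[[s]] <- tibble::tibble(
      individual_id = ids, population = origin, parent1 = parent1,
      parent2 = parent2, brood_year = brood_year, age = age)
    calls_list[[s]] <- calls
  }
  meta <- dplyr::bind_rows(rows_meta)
  truth <- dplyr::bind_rows(rows_truth)
  g <- genotype_matrix(do.call(rbind, calls_list),
                       individual_ids = meta$individual_id,
                       locus_ids = colnames(freqs))
  g <- apply_noise(g, params$error_rate, params$missing_rate)
  list(genotypes = g, meta = meta, truth = truth)
}
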