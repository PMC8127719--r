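#' Expand observed CWT recoveries to the unsampled catch
#'
#' First coded-wire-tag expansion: the observed recoveries of a population
#' in a fishery sample, corrected for tag loss, expanded to the unsampled
#' portion of the catch. `estimated = observed / (1 - tag_loss) *
#' (total_catch / sampled)`; e.g. 20 tags in a 1000-fish sample of a
#' 5000-fish catch give 20 x (5000/1000) = 100 estimated tags.
#'
#' @param observed observed number of tags.
#' @param sampled number of fish sampled.
#' @param total_catch total fishery catch.
#' @param tag_loss estimated tag-loss rate in `[0, 1)`; applied to the
#'   observed count before the sampling expansion.
#' @return estimated number of tags had the entire catch been sampled.
#' @export
cwt_estimated <- function(observed, sampled, total_catch, tag_loss = 0) {
  stopifnot(all(observed >= 0), all(sampled > 0), all(total_catch >= 0),
            all(tag_loss >= 0), all(tag_loss < 1))
  if (any(sampled > total_catch)) stop("sampled catch exceeds total catch")
  observed / (1 - tag_loss) * (total_catch / sampled)
}

#' Expand estimated tags to the unmarked portion of the release
#'
#' Second CWT expansion: estimated tags divided by the juvenile marking
#' rate give the population's total contribution to the catch; the
#' expansion is capped so it never exceeds the total number released, with
#' a `capped` flag recording the adjustment.
#'
#' @param estimated estimated tags from [cwt_estimated()].
#' @param marking_rate proportion of juveniles marked, in `(0, 1]`.
#' @param total_release total juveniles released (cap); `Inf` disables.
#' @return tibble with `expanded` and logical `capped`.
#' @export
cwt_expanded <- function(estimated, marking_rate, total_release = Inf) {
  stopifnot(all(estimated >= 0), all(marking_rate > 0), all(marking_rate <= 1),
            all(total_release >= 0))
  raw <- estimated / marking_rate
  capped <- raw > total_release
  if (any(capped)) {
    warning(sprintf("%d expansion(s) exceeded the total release and were capped",
                    sum(capped)))
  }
  tibble::tibble(expanded = pmin(raw, total_release), capped = capped)
}

#' Population-specific catch from monthly stock compositions
#'
#' Multiplies the catch of each fishery x month stratum by that stratum's
#' stock-composition estimate and sums over strata: catch for a population
#' is summed over all fisheries. Strata without a composition estimate are
#' pooled to the nearest sampled month within the same fishery (with a
#' warning); months must then be integers.
#'
#' @param ledger tibble with columns `fishery`, `month`, `catch`.
#' @param compositions tibble with columns `fishery`, `month`,
#'   `population`, `share`; shares must sum to 1 within each stratum.
#' @param pop_map optional [population_map()]; when supplied, a CU-level
#'   table is returned as well.
#' @return list with `by_population` (tibble `population`, `catch`),
#'   `by_stratum` (per-stratum population catches) and, with `pop_map`,
#'   `by_cu`.
#' @export
catch_by_population <- function(ledger, compositions, pop_map = NULL) {
  stopifnot(all(ledger$catch >= 0))
  comp_key <- unique(compositions[, c("fishery", "month")])
  rows <- list()
  for (i in seq_len(nrow(ledger))) {
    fy <- ledger$fishery[i]; mo <- ledger$month[i]
    comp <- compositions[compositions$fishery == fy & compositions$month == mo, ]
    if (nrow(comp) == 0) {
      avail <- comp_key$month[comp_key$fishery == fy]
      if (!length(avail)) {
        stop("no composition available for fishery ", fy)
      }
      nearest <- avail[which.min(abs(as.numeric(avail) - as.numeric(mo)))]
      warning(sprintf("no composition for %s month %s; pooling to month %s",
                      fy, mo, nearest))
      comp <- compositions[compositions$fishery == fy & compositions$month == nearest, ]
    }
    if (abs(sum(comp$share) - 1) > 1e-6) {
      stop(sprintf("composition for %s month %s does not sum to 1", fy, mo))
    }
    rows[[i]] <- tibble::tibble(fishery = fy, month = mo,
                                population = comp$population,
                                catch = ledger$catch[i] * comp$share)
  }
  by_stratum <- dplyr::bind_rows(rows)
  agg <- rowsum(by_stratum$catch, group = by_stratum$population)
  by_population <- tibble::tibble(population = rownames(agg),
                                  catch = unname(agg[, 1]))
  out <- list(by_population = by_population, by_stratum = by_stratum)
  if (!is.null(pop_map)) {
    cus <- cu_of(by_population$population, pop_map)
    agg_cu <- rowsum(by_population$catch, group = cus)
    out$by_cu <- tibble::tibble(cu = rownames(agg_cu),
                                catch = unname(agg_cu[, 1]))
  }
  out
}

#' Apportion a joint catch between genetically indistinguishable populations
#'
#' Hatcheries sharing a broodstock lineage form a single genetic
#' population; their combined catch estimate is apportioned to the
#' component populations in proportion to a ratio source --- PBT
#' identification counts where available, otherwise smolt-release numbers.
#'
#' @param joint_catch combined catch of the populations.
#' @param ratio_source named non-negative numeric vector (one entry per
#'   population): PBT identification counts or release numbers.
#' @return tibble: `population`, `share`, `catch`.
#' @export
apportion_shared <- function(joint_catch, ratio_source) {
  stopifnot(joint_catch >= 0, all(ratio_source >= 0))
  tot <- sum(ratio_source)
  if (tot == 0) stop("all apportionment ratios are zero")
  share <- ratio_source / tot
  tibble::tibble(population = names(ratio_source), share = unname(share),
                 catch = unname(joint_catch * share))
}

#' Age-specific catch from PBT age ratios
#'
#' A population's catch is split across ages by the age ratios of its PBT
#' identifications, provided at least `min_count` identifications were
#' made; below the threshold no split is attempted.
#'
#' @param total_catch the population's estimated catch.
#' @param age_counts named vector of PBT identification counts by age.
#' @param min_count minimum identifications required (default 20).
#' @return tibble (`age`, `share`, `catch`) when the threshold is met,
#'   otherwise `NULL` with a message.
#' @export
age_specific_catch <- function(total_catch, age_counts, min_count = 20) {
  stopifnot(total_catch >= 0, all(age_counts >= 0))
  n <- sum(age_counts)
  if (n < min_count) {
    message(sprintf("only %d PBT identifications (< %d); no age split", n, min_count))
    return(NULL)
  }
  share <- age_counts / n
  tibble::tibble(age = as.integer(names(age_counts)), share = unname(share),
                 catch = unname(total_catch * share))
}

#' Exploitation rate
#'
#' `ER = catch / (catch + escapement)`, reported as a percentage.
#'
#' @param catch population catch (fish, or estimated CWTs).
#' @param escapement population escapement on the same scale.
#' @return percentage in `[0, 100]` (vectorized).
#' @export
exploitation_rate <- function(catch, escapement) {
  stopifnot(all(catch >= 0), all(escapement >= 0), all(catch + escapement > 0))
  100 * catch / (catch + escapement)
}

#' Compare CWT-derived and genetics-derived exploitation rates
#'
#' Pairs per-population exploitation rates from the two assessment methods
#' and reports their Pearson correlation, optionally after excluding named
#' populations (e.g. one with a known escapement-sampling artifact).
#'
#' @param er_cwt,er_genetic paired numeric vectors (same populations, same
#'   order), optionally named.
#' @param exclude population names to drop before correlating.
#' @return list with `r`, `n`, `df` and the paired `table`.
#' @export
compare_er <- function(er_cwt, er_genetic, exclude = NULL) {
  stopifnot(length(er_cwt) == length(er_genetic))
  nm <- names(er_cwt)
  if (is.null(nm)) nm <- as.character(seq_along(er_cwt))
  keep <- !nm %in% exclude
  x <- er_cwt[keep]; y <- er_genetic[keep]
  if (length(x) < 3) stop("need at least 3 paired exploitation rates")
  list(r = stats::cor(x, y), n = length(x), df = length(x) - 2L,
       table = tibble::tibble(population = nm[keep], er_cwt = unname(x),
                              er_genetic = unname(y)))
}

#' Count-weighted mean age
#'
#' @param age_counts named vector of counts by age.
#' @return weighted mean age.
#' @export
mean_age <- function(age_counts) {
  stopifnot(all(age_counts >= 0), sum(age_counts) > 0)
  ages <- as.numeric(names(age_counts))
  sum(ages * age_counts) / sum(age_counts)
}

#' Concordance of PBT ages with CWT ages
#'
#' Percentage of individuals whose PBT-inferred age matches the age
#' decoded from their coded-wire tag, from a cross-tabulated audit sample.
#'
#' @param crosstab tibble with columns `cwt_age`, `pbt_age`, `n`.
#' @return percentage concordant.
#' @export
age_concordance <- function(crosstab) {
  stopifnot(all(c("cwt_age", "pbt_age", "n") %in% names(crosstab)))
  100 * sum(crosstab$n[crosstab$cwt_age == crosstab$pbt_age]) / sum(crosstab$n)
}

#' Wild escapement from the catch-ratio estimator
#'
#' Within a fishery near the end of the season, the ratio of wild-CU catch
#' to hatchery-indicator catch is assumed to equal the same ratio in
#' escapement: `C_ws / C_hs = E_ws / E_hs`, so the unknown wild escapement
#' is `E_ws = E_hs * C_ws / C_hs`. When standard deviations of the catch
#' estimates are supplied, a first-order (delta-method) SD of `E_ws` is
#' returned, treating the two catch estimates as independent.
#'
#' @param c_ws catch of the wild component (GSI-delineated CU).
#' @param c_hs catch of the hatchery-marked indicator population.
#' @param e_hs escapement of the hatchery-marked indicator population.
#' @param sd_c_ws,sd_c_hs optional SDs of the catch estimates.
#' @return list with `e_ws` and (when SDs are given) `sd`.
#' @export
escapement_wild <- function(c_ws, c_hs, e_hs, sd_c_ws = NULL, sd_c_hs = NULL) {
  stopifnot(c_hs > 0, e_hs > 0, c_ws >= 0)
  e_ws <- e_hs * c_ws / c_hs
  out <- list(e_ws = e_ws)
  if (!is.null(sd_c_ws) && !is.null(sd_c_hs)) {
    out$sd <- sqrt((e_hs / c_hs)^2 * sd_c_ws^2 +
                     (e_hs * c_ws / c_hs^2)^2 * sd_c_hs^2)
  }
  out
}

#' Annual cost comparison of CWT and PBT assessment programs
#'
#' CWT marking cost is fish tagged times (tag + handling cost per fish)
#' plus equipment maintenance; tag recovery and reading adds a per-tag
#' recovery cost over fishery and escapement recoveries. The PBT program
#' cost is genotyping of broodstock plus fishery samples at a per-genotype
#' charge. The differential is the CWT program total minus the PBT total.
#'
#' @param fish_tagged juveniles marked with a CWT annually.
#' @param tag_cost cost of one tag (currency units).
#' @param handling_cost tag insertion and fin clipping per fish.
#' @param maintenance annual tagging/detection equipment maintenance.
#' @param tags_recovered total tags recovered annually (fisheries plus
#'   escapement).
#' @param recovery_cost cost to recover and read one tag.
#' @param broodstock_genotyped broodstock individuals genotyped annually.
#' @param fishery_genotyped fishery (and escapement) samples genotyped.
#' @param genotype_cost cost per genotype (equipment included).
#' @return list with `cwt_marking`, `cwt_recovery`, `cwt_total`,
#'   `pbt_total` and `differential` (CWT minus PBT).
#' @export
cost_model <- function(fish_tagged, tag_cost, handling_cost, maintenance,
                       tags_recovered, recovery_cost,
                       broodstock_genotyped, fishery_genotyped,
                       genotype_cost) {
  args <- c(fish_tagged, tag_cost, handling_cost, maintenance, tags_recovered,
            recovery_cost, broodstock_genotyped, fishery_genotyped, genotype_cost)
  stopifnot(all(args >= 0))
  cwt_marking <- fish_tagged * (tag_cost + handling_cost) + maintenance
  cwt_recovery <- tags_recovered * recovery_cost
  pbt_total <- (broodstock_genotyped + fishery_genotyped) * genotype_cost
  list(cwt_marking = cwt_marking,
       cwt_recovery = cwt_recovery,
       cwt_total = cwt_marking + cwt_recovery,
       pbt_total = pbt_total,
       differential = cwt_marking + cwt_recovery - pbt_total)
}
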