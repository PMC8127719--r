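#' Combine PBT assignments with GSI posterior draws
#'
#' Individuals identified by parentage are fixed at probability 1.00 for
#' their identified population (0.00 elsewhere); the remaining individuals
#' contribute through the GSI mixture draws. Combination operates on the
#' retained MCMC draws, not on summary means: each combined composition
#' draw is `(fixed PBT counts + n_gsi * theta_draw) / n`, so the reported
#' SD reflects both sample size and genetic-assignment uncertainty, and
#' with no PBT identifications the result reduces exactly to
#' [summarize_composition()].
#'
#' @param pbt accepted assignment table from [accept_assignments()] (only
#'   rows with `class != "unassigned"` contribute; pass the full table).
#' @param gsi a `mixture_result` from [gibbs_mixture()] fitted to the
#'   GSI-only individuals. May be `NULL` when every individual was
#'   PBT-assigned.
#' @param n_total genotyped sample size of the stratum; defaults to PBT
#'   rows plus GSI individuals.
#' @param stratum optional stratum label carried through.
#' @return list of class `"combined_composition"` with `draws` (retained x
#'   populations combined composition draws), `summary` tibble
#'   (`population`, `mean`, `sd`), `n_pbt`, `n_gsi`, `n_total`,
#'   `indiv_probs` (per-individual final origin probabilities) and
#'   `stratum`.
#' @export
combine_pbt_gsi <- function(pbt, gsi, n_total = NULL, stratum = NA_character_) {
  assigned <- pbt[pbt$class != "unassigned", , drop = FALSE]
  pbt_ids <- assigned$offspring_id
  gsi_ids <- if (is.null(gsi)) character(0) else rownames(gsi$indiv_posterior)
  overlap <- intersect(pbt_ids, gsi_ids)
  if (length(overlap)) {
    stop("individual(s) present in both the PBT and GSI sets: ",
         paste(utils::head(overlap, 5), collapse = ", "),
         " (pipeline ordering bug)")
  }
  n_pbt <- length(pbt_ids)
  n_gsi <- length(gsi_ids)
  if (is.null(n_total)) n_total <- n_pbt + n_gsi
  if (n_pbt + n_gsi != n_total) {
    stop("PBT-assigned and GSI individuals must partition the stratum sample")
  }
  pops <- if (is.null(gsi)) sort(unique(assigned$population)) else gsi$populations
  if (!all(assigned$population %in% pops)) {
    pops <- union(pops, assigned$population)
  }
  pbt_counts <- table(factor(assigned$population, levels = pops))
  if (is.null(gsi)) {
    draws <- matrix(as.numeric(pbt_counts) / n_total, nrow = 1,
                    dimnames = list(NULL, pops))
  } else {
    theta <- gsi$theta_draws
    if (!identical(colnames(theta), pops)) {
      extra <- matrix(0, nrow(theta), length(setdiff(pops, colnames(theta))),
                      dimnames = list(NULL, setdiff(pops, colnames(theta))))
      theta <- cbind(theta, extra)[, pops, drop = FALSE]
    }
    draws <- (matrix(as.numeric(pbt_counts), nrow(theta), length(pops),
                     byrow = TRUE) + n_gsi * theta) / n_total
    colnames(draws) <- pops
  }
  # per-individual final origin probabilities: 1.00 for PBT-identified
  indiv <- matrix(0, n_total, length(pops),
                  dimnames = list(c(pbt_ids, gsi_ids), pops))
  if (n_pbt) indiv[cbind(seq_len(n_pbt), match(assigned$population, pops))] <- 1
  if (n_gsi) {
    gp <- gsi$indiv_posterior
    indiv[n_pbt + seq_len(n_gsi), match(colnames(gp), pops)] <- gp
  }
  structure(list(
    draws = draws,
    summary = tibble::tibble(population = pops,
                             mean = unname(colMeans(draws)),
                             sd = if (nrow(draws) > 1)
                               unname(apply(draws, 2L, stats::sd))
                             else rep(0, length(pops))),
    n_pbt = n_pbt, n_gsi = n_gsi, n_total = n_total,
    indiv_probs = indiv, stratum = stratum),
    class = "combined_composition")
}

#' @export
print.combined_composition <- function(x, ...) {
  cat(sprintf("<combined_composition> %s: %d PBT + %d GSI of %d individuals\n",
              ifelse(is.na(x$stratum), "(stratum unset)", x$stratum),
              x$n_pbt, x$n_gsi, x$n_total))
  print(utils::head(x$summary[order(-x$summary$mean), ], 5))
  invisible(x)
}

#' PBT identification rate
#'
#' Proportion of genotyped individuals identified via parentage, reported
#' as a percentage.
#'
#' @param n_identified number of PBT identifications.
#' @param n_genotyped number of individuals genotyped.
#' @return percentage (0-100).
#' @export
identification_rate <- function(n_identified, n_genotyped) {
  stopifnot(n_genotyped > 0, n_identified >= 0, n_identified <= n_genotyped)
  100 * n_identified / n_genotyped
}
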