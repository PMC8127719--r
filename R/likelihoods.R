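#' Genotype observation error matrix
#'
#' Symmetric genotype-level error model: an observed call equals the true
#' genotype with probability `1 - error_rate` and is each of the other two
#' codes with probability `error_rate / 2`. The same matrix is used by the
#' noise generator, the parentage likelihoods and the GSI mixture model.
#'
#' @param error_rate per-locus genotyping error rate.
#' @return 3x3 matrix `E[true + 1, observed + 1]`.
#' @export
genotype_error_matrix <- function(error_rate) {
  stopifnot(error_rate >= 0, error_rate < 1)
  E <- matrix(error_rate / 2, 3, 3)
  diag(E) <- 1 - error_rate
  dimnames(E) <- list(true = 0:2, observed = 0:2)
  E
}

# P(true offspring dosage | parent dosages): Mendelian transmission for a
# biallelic locus. A parent with dosage g transmits the reference allele
# with probability g/2.
mendelian_prob <- function(t, gm, gf) {
  pm <- gm / 2
  pf <- gf / 2
  c(`0` = (1 - pm) * (1 - pf),
    `1` = pm * (1 - pf) + (1 - pm) * pf,
    `2` = pm * pf)[as.character(t)]
}

#' Trio transmission table with genotyping error
#'
#' Per-locus probability of the observed offspring genotype given both
#' parents' genotypes: the Mendelian transmission distribution over true
#' offspring genotypes, pushed through the observation error matrix. With
#' `error_rate = 0` this is the exact Mendelian table, including hard
#' exclusions (probability 0).
#'
#' @param error_rate per-locus genotyping error rate.
#' @return 3x3x3 array indexed `[observed + 1, mother + 1, father + 1]`.
#' @export
trio_table <- function(error_rate) {
  E <- genotype_error_matrix(error_rate)
  tab <- array(0, dim = c(3, 3, 3),
               dimnames = list(observed = 0:2, mother = 0:2, father = 0:2))
  for (gm in 0:2) for (gf in 0:2) {
    true_dist <- mendelian_prob(0:2, gm, gf)
    tab[, gm + 1, gf + 1] <- as.vector(crossprod(E, true_dist))
  }
  tab
}

#' Duo transmission table with genotyping error
#'
#' Per-locus probability of the observed offspring genotype given one
#' observed parent, the other (untyped) parent integrated out using the
#' candidate population's reference-allele frequency: the offspring
#' receives one allele from the typed parent and one drawn from the
#' population at frequency `freq`.
#'
#' @param freq reference-allele frequency (scalar or vector over loci).
#' @param error_rate per-locus genotyping error rate.
#' @return if `freq` is scalar, a 3x3 matrix `[observed + 1, parent + 1]`;
#'   otherwise a `length(freq)` x 9 matrix with column index
#'   `observed + 3 * parent + 1`.
#' @export
duo_table <- function(freq, error_rate) {
  E <- genotype_error_matrix(error_rate)
  f <- as.numeric(freq)
  out <- matrix(0, length(f), 9)
  for (gp in 0:2) {
    pp <- gp / 2
    true0 <- (1 - pp) * (1 - f)
    true1 <- pp * (1 - f) + (1 - pp) * f
    true2 <- pp * f
    for (obs in 0:2) {
      out[, obs + 3 * gp + 1] <-
        true0 * E[1, obs + 1] + true1 * E[2, obs + 1] + true2 * E[3, obs + 1]
    }
  }
  if (length(f) == 1L) {
    m <- matrix(out, 3, 3, dimnames = list(observed = 0:2, parent = 0:2))
    return(m)
  }
  out
}

# Hardy-Weinberg genotype probabilities pushed through the error matrix.
# freqs: K x L matrix of reference-allele frequencies. Returns a list of
# three K x L matrices, one per observed genotype code.
hw_obs_prob <- function(freqs, error_rate) {
  E <- genotype_error_matrix(error_rate)
  p <- freqs
  hw <- list(`0` = (1 - p)^2, `1` = 2 * p * (1 - p), `2` = p^2)
  lapply(0:2, function(obs) {
    hw[[1]] * E[1, obs + 1] + hw[[2]] * E[2, obs + 1] + hw[[3]] * E[3, obs + 1]
  })
}

drop_gm <- function(x) {
  x <- unclass(x)
  storage.mode(x) <- "integer"
  x
}

#' Trio log-likelihood of an offspring given a candidate parent pair
#'
#' Multi-locus log-likelihood of the observed offspring genotype under
#' Mendelian transmission from the two observed parents, with the
#' genotyping-error model applied to the offspring call. Loci missing in
#' any of the three genotypes are skipped (pairwise deletion).
#'
#' @param offspring,mother,father integer genotype vectors (codes 0/1/2,
#'   `NA` missing), one entry per locus.
#' @param error_rate per-locus genotyping error rate.
#' @return list with `per_locus` probabilities (NA where skipped),
#'   `loglik` (sum of logs over used loci) and `n_loci` used. A hard
#'   Mendelian exclusion at `error_rate = 0` yields `loglik = -Inf`.
#' @export
trio_likelihood <- function(offspring, mother, father, error_rate = 0.0114) {
  stopifnot(length(mother) == length(offspring),
            length(father) == length(offspring))
  tab <- trio_table(error_rate)
  use <- !is.na(offspring) & !is.na(mother) & !is.na(father)
  per_locus <- rep(NA_real_, length(offspring))
  per_locus[use] <- tab[cbind(offspring[use] + 1, mother[use] + 1, father[use] + 1)]
  list(per_locus = per_locus,
       loglik = sum(log(per_locus[use])),
       n_loci = sum(use))
}

#' Duo log-likelihood of an offspring given a single candidate parent
#'
#' As [trio_likelihood()], but with the second parent integrated out using
#' the candidate population's allele frequencies.
#'
#' @param offspring,parent integer genotype vectors per locus.
#' @param freq reference-allele frequency of the candidate's population,
#'   recycled or per locus.
#' @param error_rate per-locus genotyping error rate.
#' @return list with `per_locus`, `loglik`, `n_loci`.
#' @export
duo_likelihood <- function(offspring, parent, freq, error_rate = 0.0114) {
  stopifnot(length(parent) == length(offspring))
  freq <- rep_len(as.numeric(freq), length(offspring))
  tab <- duo_table(freq, error_rate)
  if (length(freq) == 1L) tab <- matrix(as.vector(tab), 1L, 9L)
  use <- !is.na(offspring) & !is.na(parent)
  per_locus <- rep(NA_real_, length(offspring))
  idx <- offspring[use] + 3 * parent[use] + 1
  per_locus[use] <- tab[cbind(which(use), idx)]
  list(per_locus = per_locus,
       loglik = sum(log(per_locus[use])),
       n_loci = sum(use))
}

#' Per-population log-likelihood of sampled genotypes
#'
#' Log-likelihood of each individual's multi-locus genotype under
#' Hardy-Weinberg proportions at each baseline population's (smoothed)
#' allele frequencies, with the shared genotyping-error matrix applied.
#' Missing calls are skipped. This is the individual-level engine of the
#' GSI mixture model.
#'
#' @param g a [genotype_matrix()] of mixture individuals.
#' @param freqs K x L matrix of population reference-allele frequencies
#'   (rows = populations, columns = loci in the order of `g`).
#' @param error_rate per-locus genotyping error rate.
#' @return n x K matrix of log-likelihoods.
#' @export
population_loglik <- function(g, freqs, error_rate = 0.0114) {
  m <- drop_gm(g)
  if (ncol(m) != ncol(freqs)) stop("locus dimensions of genotypes and frequencies differ")
  obs_prob <- hw_obs_prob(freqs, error_rate)  # list of K x L
  out <- matrix(0, nrow(m), nrow(freqs),
                dimnames = list(rownames(m), rownames(freqs)))
  for (code in 0:2) {
    ind <- !is.na(m) & m == code
    storage.mode(ind) <- "double"
    lp <- log(obs_prob[[code + 1]])
    # impossible genotypes (unsmoothed fixed loci at error 0) get a finite
    # floor so the matrix product stays defined; they still normalize to 0
    lp[!is.finite(lp)] <- log(.Machine$double.xmin)
    out <- out + ind %*% t(lp)
  }
  out
}
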