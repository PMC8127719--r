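#' Per-population allele frequencies
#'
#' Reference-allele frequency per population and locus with an optional
#' symmetric pseudocount (Dirichlet smoothing), as used by both the GSI
#' mixture model and the single-parent likelihood:
#' `(allele count + pseudocount) / (2 * n_called + 2 * pseudocount)`.
#' A locus with no calls in a population falls back to the prior mean 0.5
#' (undefined with `pseudocount = 0`, returned as `NaN`).
#'
#' @param g a [genotype_matrix()] of baseline individuals.
#' @param labels population label per individual (same order as rows).
#' @param pseudocount per-allele smoothing constant (default 0.5).
#' @return K x L matrix of frequencies, rows named by population.
#' @export
allele_frequencies <- function(g, labels, pseudocount = 0.5) {
  m <- drop_gm(g)
  pops <- if (is.factor(labels)) levels(labels) else unique(as.character(labels))
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(m))
  empty <- setdiff(pops, labels)
  if (length(empty)) stop("empty population(s): ", paste(empty, collapse = ", "))
  K <- length(pops)
  counts <- matrix(0, K, ncol(m), dimnames = list(pops, colnames(m)))
  called <- counts
  for (k in seq_len(K)) {
    sub <- m[labels == pops[k], , drop = FALSE]
    counts[k, ] <- colSums(sub, na.rm = TRUE)
    called[k, ] <- colSums(!is.na(sub))
  }
  (counts + pseudocount) / (2 * called + 2 * pseudocount)
}

#' Expected and observed heterozygosity by locus
#'
#' `He` is the Hardy-Weinberg expected heterozygosity `2p(1-p)` computed
#' from the pooled (overall) allele frequency across the baseline; `Ho` is
#' the fraction of called genotypes that are heterozygous.
#'
#' @param g a [genotype_matrix()].
#' @param labels optional population labels; only used to check coverage.
#' @return tibble with columns `locus`, `he`, `ho`, `n_called`.
#' @export
heterozygosities <- function(g, labels = NULL) {
  m <- drop_gm(g)
  called <- colSums(!is.na(m))
  p <- colSums(m, na.rm = TRUE) / (2 * called)
  he <- 2 * p * (1 - p)
  ho <- colSums(m == 1L, na.rm = TRUE) / called
  tibble::tibble(locus = colnames(m), he = unname(he), ho = unname(ho),
                 n_called = unname(called))
}

#' Weir-Cockerham F_ST per locus
#'
#' Moment (variance-partitioning) estimator of differentiation among
#' population samples for a biallelic locus, unbiased for unequal sample
#' sizes: theta = a / (a + b + c) with among-population (a), among-
#' individual-within-population (b) and within-individual (c) variance
#' components computed from sample sizes n_i, sample allele frequencies
#' p_i and observed heterozygote proportions h_i:
#'
#'   n_bar = mean(n_i); n_c = (r*n_bar - sum(n_i^2)/(r*n_bar)) / (r - 1)
#'   p_bar = sum(n_i p_i) / (r n_bar); s2 = sum(n_i (p_i - p_bar)^2) / ((r-1) n_bar)
#'   h_bar = sum(n_i h_i) / (r n_bar)
#'   a = (n_bar/n_c) * (s2 - (p_bar(1-p_bar) - s2 (r-1)/r - h_bar/4) / (n_bar-1))
#'   b = (n_bar/(n_bar-1)) * (p_bar(1-p_bar) - s2 (r-1)/r - h_bar (2 n_bar - 1)/(4 n_bar))
#'   c = h_bar / 2
#'
#' Negative estimates (sampling noise around zero differentiation) are
#' reported as computed, not truncated.
#'
#' @param g a [genotype_matrix()] of baseline individuals.
#' @param labels population label per individual.
#' @return tibble with columns `locus`, `fst`, and the variance components
#'   `a`, `b`, `c`. Monomorphic loci give `NaN`.
#' @export
fst_per_locus <- function(g, labels) {
  m <- drop_gm(g)
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(m))
  pops <- unique(labels)
  r <- length(pops)
  if (r < 2) stop("F_ST requires at least two populations")
  L <- ncol(m)
  n_i <- matrix(0, r, L); p_i <- matrix(0, r, L); h_i <- matrix(0, r, L)
  for (k in seq_len(r)) {
    sub <- m[labels == pops[k], , drop = FALSE]
    n_i[k, ] <- colSums(!is.na(sub))
    p_i[k, ] <- colSums(sub, na.rm = TRUE) / (2 * n_i[k, ])
    h_i[k, ] <- colSums(sub == 1L, na.rm = TRUE) / n_i[k, ]
  }
  n_bar <- colMeans(n_i)
  n_c <- (r * n_bar - colSums(n_i^2) / (r * n_bar)) / (r - 1)
  p_bar <- colSums(n_i * p_i) / (r * n_bar)
  s2 <- colSums(n_i * (p_i - rep(p_bar, each = r))^2) / ((r - 1) * n_bar)
  h_bar <- colSums(n_i * h_i) / (r * n_bar)
  a <- (n_bar / n_c) *
    (s2 - (p_bar * (1 - p_bar) - s2 * (r - 1) / r - h_bar / 4) / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - s2 * (r - 1) / r - h_bar * (2 * n_bar - 1) / (4 * n_bar))
  cc <- h_bar / 2
  tibble::tibble(locus = colnames(m), fst = a / (a + b + cc),
                 a = a, b = b, c = cc)
}

#' Locus summary statistics table
#'
#' Convenience wrapper joining heterozygosities and per-locus F_ST, the
#' shape used for baseline characterization reports.
#'
#' @inheritParams fst_per_locus
#' @return tibble: `locus`, `fst`, `he`, `ho`.
#' @export
locus_stats <- function(g, labels) {
  het <- heterozygosities(g)
  fst <- fst_per_locus(g, labels)
  dplyr::left_join(fst[, c("locus", "fst")], het, by = "locus")
}
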