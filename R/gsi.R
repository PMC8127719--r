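#' Conditional Bayesian mixture model for stock composition
#'
#' Gibbs sampler for genetic stock identification: baseline allele
#' frequencies are held fixed at their (pseudocount-smoothed) estimates,
#' and the chain alternates between (a) sampling each mixture individual's
#' population of origin from its conditional posterior (proportional to
#' the mixture proportion times the individual's population likelihood)
#' and (b) sampling the mixture proportion vector from the Dirichlet
#' posterior implied by the current origin counts, with a symmetric
#' Dirichlet(1/K) prior. The retained draws are the last `retained`
#' iterations of the chain, following the operational 25,000 / 5,000
#' burn-in / last-5,000 scheme.
#'
#' Individuals with zero likelihood in every population are given a
#' uniform origin posterior and flagged with a message.
#'
#' @param sample a [genotype_matrix()] of mixture individuals.
#' @param freqs K x L baseline frequency matrix (pseudocount-smoothed),
#'   rows named by population; loci aligned with `sample`.
#' @param config a [run_config()] (iterations, burn-in, retained draws,
#'   error rate).
#' @param seed optional seed.
#' @return a `mixture_result`: list with `theta_draws` (retained x K
#'   mixture-proportion draws), `indiv_posterior` (n x K per-individual
#'   origin probabilities averaged over retained draws), `populations`,
#'   and `loglik` (the fixed n x K log-likelihood matrix).
#' @export
gibbs_mixture <- function(sample, freqs, config = run_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  K <- nrow(freqs)
  n <- nrow(sample)
  if (K < 1L) stop("baseline must contain at least one population")
  if (n < 1L) stop("mixture sample is empty")
  ll <- population_loglik(sample, freqs, config$error_rate)
  # center rows for stable exponentiation; all-(-Inf) rows become uniform
  rmax <- apply(ll, 1L, max)
  dead <- !is.finite(rmax)
  if (any(dead)) {
    message(sprintf("gibbs_mixture: %d individual(s) with zero likelihood in all populations; assigned uniform posterior", sum(dead)))
    ll[dead, ] <- 0
    rmax[dead] <- 0
  }
  U <- exp(ll - rmax)          # n x K, rows bounded by 1

  iters <- config$iterations
  first_kept <- iters - config$retained + 1L
  alpha <- rep(1 / K, K)
  theta <- rep(1 / K, K)
  theta_draws <- matrix(NA_real_, config$retained, K,
                        dimnames = list(NULL, rownames(freqs)))
  post_accum <- matrix(0, n, K, dimnames = list(rownames(sample), rownames(freqs)))
  kept <- 0L
  for (it in seq_len(iters)) {
    W <- U * rep(theta, each = n)
    tot <- rowSums(W)
    # inverse-CDF categorical draw, one uniform per individual
    cs <- W %*% upper.tri(diag(K), diag = TRUE)
    z <- rowSums(cs < stats::runif(n) * tot) + 1L
    counts <- tabulate(z, nbins = K)
    gam <- stats::rgamma(K, shape = alpha + counts)
    theta <- gam / sum(gam)
    if (it >= first_kept) {
      kept <- kept + 1L
      theta_draws[kept, ] <- theta
      P <- W / tot
      post_accum <- post_accum + P
    }
  }
  structure(list(theta_draws = theta_draws,
                 indiv_posterior = post_accum / kept,
                 populations = rownames(freqs),
                 loglik = ll),
            class = "mixture_result")
}

#' @export
print.mixture_result <- function(x, ...) {
  cat(sprintf("<mixture_result> %d individuals, %d populations, %d retained draws\n",
              nrow(x$indiv_posterior), length(x$populations),
              nrow(x$theta_draws)))
  invisible(x)
}

#' Posterior mean and SD of stock composition
#'
#' Summarizes the retained mixture-proportion draws per population; the
#' standard deviation over retained draws is the reported uncertainty of
#' the stock-composition estimate.
#'
#' @param result a `mixture_result` from [gibbs_mixture()].
#' @return tibble: `population`, `mean`, `sd`.
#' @export
summarize_composition <- function(result) {
  draws <- result$theta_draws
  tibble::tibble(population = colnames(draws),
                 mean = unname(colMeans(draws)),
                 sd = unname(apply(draws, 2L, stats::sd)))
}

#' Maximum-posterior population per individual
#'
#' @param result a `mixture_result`.
#' @return tibble: `individual_id`, `population`, `posterior`.
#' @export
map_population <- function(result) {
  P <- result$indiv_posterior
  idx <- max.col(P, ties.method = "first")
  tibble::tibble(individual_id = rownames(P),
                 population = colnames(P)[idx],
                 posterior = P[cbind(seq_len(nrow(P)), idx)])
}

#' Aggregate a population-level composition to conservation units
#'
#' Stock composition by CU is the sum of the allocations to all baseline
#' populations belonging to the CU. Accepts either a summary tibble (with
#' `population` and `mean`, and optionally per-draw input) or a draws
#' matrix; for draws, CU shares are summed per draw so the CU-level SD is
#' exact rather than assembled from population SDs.
#'
#' @param composition tibble with columns `population` and `mean` (plus
#'   optional `sd`), or a draws matrix with population columns.
#' @param pop_map a [population_map()].
#' @return tibble: `cu`, `mean` (and `sd` when draws were supplied).
#' @export
aggregate_to_cu <- function(composition, pop_map) {
  if (is.matrix(composition)) {
    cus <- cu_of(colnames(composition), pop_map)
    agg <- t(rowsum(t(composition), group = cus))
    return(tibble::tibble(cu = colnames(agg), mean = unname(colMeans(agg)),
                          sd = unname(apply(agg, 2L, stats::sd))))
  }
  cus <- cu_of(composition$population, pop_map)
  means <- rowsum(composition$mean, group = cus)
  tibble::tibble(cu = rownames(means), mean = unname(means[, 1]))
}
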