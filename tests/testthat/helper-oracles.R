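# Independent brute-force oracles: explicit enumeration over parental
# gametes and error outcomes, written without reference to the package's
# table-based implementation.

allele_pairs <- function(g) switch(g + 1, c(0L, 0L), c(0L, 1L), c(1L, 1L))

err_term <- function(true, obs, eps) if (true == obs) 1 - eps else eps / 2

oracle_trio <- function(go, gm, gf, eps) {
  p <- 0
  for (a in allele_pairs(gm)) for (b in allele_pairs(gf)) {
    p <- p + 0.25 * err_term(a + b, go, eps)
  }
  p
}

oracle_duo <- function(go, gp, q, eps) {
  p <- 0
  for (a in allele_pairs(gp)) for (b in 0:1) {
    p <- p + 0.5 * (if (b == 1) q else 1 - q) * err_term(a + b, go, eps)
  }
  p
}

oracle_hw_obs <- function(go, q, eps) {
  hw <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  sum(hw * vapply(0:2, function(t) err_term(t, go, eps), numeric(1)))
}
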