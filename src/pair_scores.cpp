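#include <Rcpp.h>
using namespace Rcpp;

// Log-likelihood-ratio scores of every offspring against every candidate
// parent pair, relative to the unrelated-baseline hypothesis accumulated
// over exactly the same loci (pairwise deletion keeps the hypotheses
// comparable when genotypes have different missing patterns).
//
// offT, parT : L x n integer matrices (loci in rows), codes 0/1/2, NA missing
// pa, pb     : 0-based column indices into parT, one entry per pair
// logT       : length-27 vector, index obs + 3*gm + 9*gf
// logU       : L x 3 matrix, log baseline probability of the observed
//              offspring genotype (the unrelated hypothesis)
// min_shared : comparisons with fewer jointly called loci score NA
// keep       : nO x nPar logical screen; a pair is only scored for an
//              offspring when both members pass (screened-out pairs give
//              NA, i.e. a negligible likelihood contribution)
// [[Rcpp::export]]
List trio_pair_scores_cpp(IntegerMatrix offT, IntegerMatrix parT,
                          IntegerVector pa, IntegerVector pb,
                          NumericVector logT, NumericMatrix logU,
                          int min_shared, LogicalMatrix keep) {
  const int L = offT.nrow(), nO = offT.ncol(), nP = pa.size();
  NumericMatrix llr(nO, nP);
  IntegerMatrix shared(nO, nP);
  std::fill(llr.begin(), llr.end(), NA_REAL);
  std::vector<int> combo(L);
  for (int j = 0; j < nP; ++j) {
    const int m = pa[j], f = pb[j];
    bool any_i = false;
    for (int i = 0; i < nO; ++i) {
      if (keep(i, m) && keep(i, f)) { any_i = true; break; }
    }
    if (!any_i) continue;
    for (int l = 0; l < L; ++l) {
      const int gm = parT(l, m), gf = parT(l, f);
      combo[l] = (gm == NA_INTEGER || gf == NA_INTEGER) ? -1 : 3 * gm + 9 * gf;
    }
    for (int i = 0; i < nO; ++i) {
      if (!(keep(i, m) && keep(i, f))) continue;
      double s = 0.0;
      int cnt = 0;
      for (int l = 0; l < L; ++l) {
        const int go = offT(l, i);
        if (go == NA_INTEGER || combo[l] < 0) continue;
        s += logT[go + combo[l]] - logU(l, go);
        ++cnt;
      }
      llr(i, j) = (cnt >= min_shared) ? s : NA_REAL;
      shared(i, j) = cnt;
    }
  }
  return List::create(_["llr"] = llr, _["shared"] = shared);
}

// Single-parent (duo) scores against a set of candidate parents from one
// population, whose untyped mate is integrated out at that population's
// allele frequencies.
//
// logD : L x 9 matrix, column index obs + 3*gp, log duo probability
// [[Rcpp::export]]
List duo_parent_scores_cpp(IntegerMatrix offT, IntegerMatrix parT,
                           IntegerVector pidx, NumericMatrix logD,
                           NumericMatrix logU, int min_shared) {
  const int L = offT.nrow(), nO = offT.ncol(), nP = pidx.size();
  NumericMatrix llr(nO, nP);
  IntegerMatrix shared(nO, nP);
  for (int j = 0; j < nP; ++j) {
    const int pcol = pidx[j];
    for (int i = 0; i < nO; ++i) {
      double s = 0.0;
      int cnt = 0;
      for (int l = 0; l < L; ++l) {
        const int go = offT(l, i), gp = parT(l, pcol);
        if (go == NA_INTEGER || gp == NA_INTEGER) continue;
        s += logD(l, go + 3 * gp) - logU(l, go);
        ++cnt;
      }
      llr(i, j) = (cnt >= min_shared) ? s : NA_REAL;
      shared(i, j) = cnt;
    }
  }
  return List::create(_["llr"] = llr, _["shared"] = shared);
}
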