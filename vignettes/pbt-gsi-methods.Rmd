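---
title: "Methods: parentage-based tagging with genetic stock identification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: parentage-based tagging with genetic stock identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbtgsi)
```

## The assessment problem

Mixed-stock Pacific salmon fisheries intercept fish from hundreds of
populations at once. Managing them under conservation-unit (CU) based
policy requires knowing, for each fishery and month, which populations
the catch came from, how old the fish were, and what fraction of each
population's production was harvested. The traditional instrument is
the coded-wire tag (CWT): a physical tag placed in a fraction of
hatchery juveniles, recovered by killing and beheading sampled fish.
`pbtgsi` implements the genetics-based alternative, which combines two
identification methods applied to a tissue sample:

* **Parentage-based tagging (PBT).** Every hatchery broodstock fish is
  genotyped at a SNP panel. Any fish sampled later whose parents are in
  that register can be assigned to its parent pair, which reveals both
  its hatchery of origin and its age (sampling year minus brood year).
* **Genetic stock identification (GSI).** Fish not identified by PBT
  are assigned probabilistically to baseline populations from their
  multi-locus genotypes via a Bayesian mixture model over the baseline
  allele frequencies.

The two are combined into a single stock-composition estimate per
fishery stratum, which then drives the assessment arithmetic: catch by
population and CU, age-specific catch, exploitation rates, and a
comparison against CWT-derived figures.

## Genotypes and quality control

Genotypes are diploid biallelic SNP calls coded 0/1/2 (copies of the
reference allele) with an explicit missing code, held in a
`genotype_matrix`. An individual must be successfully genotyped at a
minimum number of loci to be used at all (`qc_min_loci()`, default 150
of the 389-SNP panel); the filter is idempotent and monotone in its
threshold. A single symmetric error model is used everywhere: an
observed call equals the true genotype with probability $1-\varepsilon$
and is each wrong code with probability $\varepsilon/2$, with
$\varepsilon = 0.0114$ by default — the rate estimated from re-genotyping
the same individuals twice (1839 discrepancies in 161,280 single-locus
comparisons). Using the same matrix in the simulator, the parentage
likelihoods and the mixture model keeps the system internally
consistent.

## Parentage likelihoods

For a candidate parent pair with observed genotypes $g_m, g_f$ and an
offspring observed as $g_o$, the per-locus trio likelihood is

$$P(g_o \mid g_m, g_f) = \sum_{t \in \{0,1,2\}} M(t \mid g_m, g_f)\,
E(g_o \mid t),$$

where $M$ is Mendelian transmission (each parent passes a reference
allele with probability $g/2$) and $E$ the error matrix applied to the
offspring's observation. At $\varepsilon = 0$ this is the exact
Mendelian table including hard exclusions. The single-parent (duo)
likelihood integrates the untyped mate out over the candidate
population's allele frequencies. Parental genotypes are taken at face
value; with $\varepsilon > 0$ the offspring-side error term also absorbs
isolated parental miscalls, and at $\varepsilon = 0$ a configurable
per-locus floor (`likelihood_floor`, default $10^{-9}$, disabled when
$\varepsilon > 0$) prevents one bad call from zeroing a true family.

Loci missing in any genotype involved are skipped (pairwise deletion),
with a minimum of 100 jointly called loci per comparison. Because
different candidates have different missing patterns, every comparison
is expressed as a log-likelihood *ratio* against an unrelated-fish
hypothesis accumulated over exactly the same loci; the unrelated
hypothesis uses the equal-weight mixture of Hardy–Weinberg genotype
probabilities across the baseline populations, i.e. the genotype
distribution of a random baseline fish. The ratios are converted to
assignment probabilities under a flat prior over candidates with mass
`unrelated_prior` (default 0.5) on the unrelated hypothesis. A
tagging-rate-derived prior ($1-p^2$) can be supplied when a single
broodstock genotyping proportion $p$ applies; fishery samples mix
populations with different $p$, so the neutral default is used there.

Scoring runs per brood year, which restricts two-parent assignments to
crosses that could actually have happened and fixes the implied age.
Evaluating every within-population parent pair scales quadratically, so
pairs are only scored when both members individually beat the unrelated
hypothesis as single parents (`pair_screen_llr = 0`); a skipped pair's
likelihood contribution is of order $e^{-100}$ and the resulting
probabilities are numerically identical to the exhaustive computation
(verified in the test suite), at roughly 25-fold less cost.

## Acceptance rules

Candidates across brood years are resolved per offspring in a fixed
order:

1. a **two-parent** assignment is accepted when both parents are from
   the same population and brood year and its probability is at least
   `accept_prob` (0.95); it takes precedence over single-parent
   candidates in other years;
2. among **single-parent** candidates in competing brood years, the
   highest probability must meet the threshold *and* exceed the
   runner-up by at least `single_parent_margin` (0.05);
3. a surviving single-parent candidate must agree with the
   individual's GSI assignment at the CU level (maximum-posterior
   population, one of the design points left open by the source
   material; the posterior mean allocation would differ only for
   near-tied populations). Individuals without a GSI posterior have the
   candidate rejected.

Candidates whose implied age falls outside the configured range (2–6
years for fishery samples) are ineligible. Everything unresolved is
passed to GSI-only treatment.

## The conditional mixture model

GSI uses a conditional Bayesian mixture: baseline allele frequencies
are held fixed at pseudocount-smoothed estimates (0.5 per allele), and a
Gibbs sampler alternates between drawing each individual's origin
$z_i \sim \Pr(z_i = k) \propto \theta_k L_{ik}$ and the mixture vector
$\theta \sim \mathrm{Dirichlet}(\alpha + \text{counts})$ with a
symmetric prior $\alpha_k = 1/K$. The likelihood $L_{ik}$ is the
Hardy–Weinberg genotype probability pushed through the same error
matrix. The chain follows the operational schedule literally: 25,000
iterations, 5,000 burn-in, and the *last* 5,000 draws retained (the
middle draws are discarded exactly as in the source protocol; the
schedule is configurable since nothing downstream depends on the gap).
Posterior means and SDs over the retained $\theta$ draws are the
stock-composition estimate and its uncertainty; CU-level compositions
sum population allocations per draw so CU SDs are exact.

Two numerical notes. Individuals with zero likelihood in every
population receive a uniform posterior and a logged message. And
because origins are drawn by inverse-CDF, permuting the baseline order
changes the random-number alignment; exchangeability therefore holds in
distribution and is tested statistically rather than bit-for-bit.

## Combining PBT and GSI

PBT-identified fish are fixed at probability 1.00 for their identified
population. Combination happens on the retained draws, not on summary
means: with $n_{\mathrm{PBT}}$ fixed counts $c$ and $n_{\mathrm{GSI}}$
fish behind the mixture draws $\theta^{(s)}$, the combined composition
draw is $(c + n_{\mathrm{GSI}}\theta^{(s)})/n$. The reported SD thus
reflects both the genetic-assignment uncertainty and the relative
sample sizes; with no PBT identifications it reduces exactly to the
GSI summary, and adding PBT identifications can only shrink the SD.

## Assessment arithmetic

The downstream operations are deliberately plain:

* CWT expansions: observed tags are corrected for tag loss
  (`observed/(1-loss)`, applied before the sampling expansion — the
  algebraic placement is a package choice, the correction itself being
  standard), expanded by `catch/sampled`, then optionally by the
  juvenile marking rate with a cap at the total release.
* Catch by population: monthly stratum catch times the stratum's
  composition, summed over fisheries; total catch is conserved exactly.
  Strata without a composition pool to the nearest sampled month within
  the fishery, with a warning.
* Genetically indistinguishable hatchery pairs (shared broodstock
  lineages) have their combined catch apportioned by PBT identification
  counts where available, otherwise by smolt-release ratios.
* Age-specific catch uses PBT age ratios only where at least 20
  identifications exist.
* Exploitation rate is `catch/(catch+escapement)`; CWT-vs-genetics
  comparisons use Pearson correlation on the published total rates.
* The wild-escapement estimator assumes the wild-to-indicator catch
  ratio equals the same ratio in escapement; a delta-method SD is
  offered and checked against Monte-Carlo in the tests.
* The cost model prices CWT marking (tag + handling per fish, plus
  equipment maintenance), tag recovery, and PBT genotyping. Note that
  the published program total and differential are $500 higher than the
  sum of the published components; the package reports the
  component-implied values ($1{,}791{,}250$ total, $931{,}250$
  differential).

## What the simulator emulates — and what it does not

`sim_params()` defaults *are* the study conditions at desk scale: 16
populations (vs several hundred coastwide) × 389 SNPs, 100 baseline
fish per population, five brood years of broodstock with configurable
genotyping success, Balding–Nichols divergence $F = 0.05$ around
uniform ancestral frequencies (a typical within-region SNP divergence;
an optional two-level CU/population hierarchy is available but has no
source-derived default), Hardy–Weinberg genotypes within population,
polygamous within-population-year matings, fishery mixtures over ages
2–6, and the shared error/missingness model. Problem sizes used in the
tests and the acceptance script (1,500 fishery fish, 400-fish mixture
recovery, 20 calibration replicates at reduced chain length) were
chosen as the smallest scales at which the targeted properties are
statistically meaningful.

The simulator does *not* emulate linkage between loci, genotyping
error that varies by locus or batch, family-size variation within
matings, population structure within a baseline population,
close-relative structure between populations (the main real-world
source of cross-year single-parent confusion), or misassigned baseline
samples. Passing tests therefore demonstrate the correctness of the
machinery and its statistical behaviour under the stated model, not
the field performance of any particular panel.

## Known limitations

* Parental genotypes enter the trio likelihood as observed; a fully
  symmetric treatment would integrate over parental true genotypes
  given population frequencies, at roughly ninefold cost per locus.
* The unrelated hypothesis uses an equal-weight baseline mixture; a
  stratum-specific mixture weight would sharpen it slightly.
* The conditional model holds baseline frequencies fixed; baselines
  with very small samples would warrant the fully Bayesian variant.
* Sex is not tracked in broodstock registers, so "pairs" are unordered;
  hatchery cross records with sex would halve the candidate-pair space.
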