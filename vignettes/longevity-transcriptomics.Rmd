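---
title: "Methods: phylogenetic comparative transcriptomics of longevity"
author: "longevitr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetic comparative transcriptomics of longevity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Comparing gene expression across dozens of mammal species against
life-history traits -- maximum lifespan (ML), female time to maturity
(FTM), and their weight-corrected residuals (MLres, FTMres) -- asks a
regression question with two complications that ordinary tooling ignores:

1. Species are not independent observations: residual expression variation
   is phylogenetically structured, so error covariance must come from the
   tree.
2. With ~100 species a single aberrant species can manufacture or destroy
   a per-gene association, so pointwise P values need an explicit
   robustness construction, and family-wise error needs a permutation
   adjustment rather than a rank-based correction.

`longevitr` implements the full path from orthologous fragment counts to
IU/RU/ID/RD gene classes, with a synthetic-data generator that stands in
for the unavailable raw data and carries ground-truth labels for every
calling step.

# Normalization and specificity

Counts are filtered (low expression: value < 10 in >= 4 observed samples;
dominant genes: >= 5% of the grand total; orthologs in fewer than
`min_species` species, 68 at full scale), then normalized as
`log2(TMM-RPKM + 1)`.  TMM factors are computed natively: reference =
sample whose 75th-percentile count/library is closest to the mean, log
ratios trimmed 30% (M) and 5% (A), inverse-variance weights, factors
normalized to multiply to one.  The trim constants are the standard
defaults; the source analysis names only the method.  An absent ortholog
is a masked cell, never a zero count: filters and regressions exclude
masked cells from numerator and denominator alike.

Species specificity uses Tau: with per-species means `v_i` and
`x_i = v_i / max_j v_j`, `tau = sum(1 - x_i) / (N - 1)`; 0 = uniform,
1 = single-species, `< 0.2` broad, `> 0.8` specific.  The normalization by
the maximum is the standard specificity-index convention (the inline
formula in the source omits it, but without it tau is unbounded and the
thresholds meaningless); ties at the maximum each get `x = 1`; an all-zero
gene is flagged undefined rather than scored 0.  PCA runs on the 5,000
highest-variance genes, covariance-based on centered log values (the
scaling is not stated in the source; covariance is the common choice),
with per-gene mean completion of masked cells for the decomposition only.

# Life-history imputation

Missing trait values are imputed under a joint Brownian-motion model: log
traits are multivariate normal with covariance
`R (x) C_tree + diag(noise)`, where `R` is the between-trait covariance
and `C_tree` the depth-scaled BM correlation from the tree.  Parameters
are estimated by REML (default; ML switch available), and missing cells
are filled with conditional expectations given every observed cell --
phylogenetic proximity and cross-trait correlation both inform the
estimate.  Observed cells are returned byte-identical.  Two baselines
(grand mean, predictive mean matching with optional PCoA eigenvector
covariates) feed the evaluation harness, which sweeps the missingness
grid 5-50% under three mechanisms: MCAR, weight-dependent (MAR_AW, small-
vs large-weight species split at the median, ML 82.43%/17.57% and FTM
62.34%/37.66% of deletions), and distance-dependent (MAR_HD, split at
half the maximum patristic distance to a reference species, defaulting to
a "human"-named tip, else the first tip alphabetically).  Scores:

* NRMSE = RMSE over originally-missing cells / range of the true trait,
  computed on the log scale (as a ratio it is invariant to the log base).
  The source formula mixes X and Y symbols in the denominator; both are
  read as the true values of the scored trait.
* Slope bias = |allometric slope before minus after imputation| -- a check
  that imputation preserves the biological signal, not just pointwise
  accuracy.

PCoA axes with non-positive eigenvalues (tree metrics need not embed in
Euclidean space) are truncated, with the retained-variance fraction
recorded.  External imputation engines (chained equations, random
forests) are out of scope by design: the selected BM conditional-mean
method and the harness are the reusable computation.

# Per-gene association

For each gene and trait, three residual models are fitted on the species
where the gene exists (masked species excluded; tree pruned per gene):
OLS (iid), BM (covariance proportional to shared root path), and
stationary OU with covariance
`exp(-alpha d_ij) (1 - exp(-2 alpha C_ij)) / (2 alpha)`, which recovers BM
as `alpha -> 0` and independence as `alpha -> infinity`.  `alpha` is
profiled over log-spaced bounds `c(1e-3, 100)/depth` (coarse grid plus
golden-section refinement to ~5% relative resolution -- the likelihood is
flat beyond that).  Model choice is by AIC; a raw-ML switch reproduces a
literal maximum-likelihood selection but, because OU nests BM, raw ML
always weakly prefers OU, which is why AIC is the default.  Exact ties go
to the simpler model (OLS < BM < OU).  Degenerate zero-residual fits
return P = 1 with a flag, not P = 0.

Absolute traits are log2-scaled before regression; residual traits, which
can be negative, enter untransformed (logging them is undefined; the
interaction with the source's stated log2 scaling is ambiguous and
documented here as a choice).

**Two-step robust P.**  Step 1: fit, drop the single species with the
largest absolute raw residual, refit -> `P_robust`.  Step 2: from the
step-1 set, drop each remaining species in turn, refit, take the largest
P -> `P_max`.  The model is re-selected at every refit by default
(`reselect = FALSE` holds it fixed).  Genes below a 6-species floor are
skipped with a reason (the source states no floor; 6 is the smallest n
where the step-2 refits retain 2 residual df).

**maxT adjustment.**  The trait is permuted across the species panel
(n_perm times, one shared permutation set for all genes so inter-gene
dependence is preserved), both robust statistics are recomputed per gene
per permutation, and step-down Westfall-Young adjusted P values are
formed from the per-permutation maxima; `P >= 1/(n_perm+1)` always.
Per-permutation statistics hold each gene's model fixed at its observed
choice: re-selecting among three models inside every
`n_perm x n_genes x n_species` refit is computationally out of reach, and
the fixed-model engine is verified against a brute-force GLS path in the
tests.  The engine itself avoids refitting: for a fixed inverse
covariance `A`, every single-species deletion is a Schur-complement
rank-one correction, so the full leave-one-out chain costs O(n) per
permutation.  BH adjustment is available as a fallback switch.  Plain
trait shuffling ignores phylogeny; a practitioner worried about
anticonservatism under strong trait signal should raise `n_perm` and
inspect the per-gene permutation P values, which are reported alongside.

A gene is trait-significant iff `P_robust.adj < 0.005` and
`P_max.adj < 0.05` (strict), and longevity-correlated iff significant for
at least two of the four longevity traits; direction is the majority
slope sign, with exact conflicts flagged.

# Enrichment and selection integration

SUMSTAT enrichment scores a gene set by the sum of member scores
(directional PGLS slopes with the off-direction zeroed, or Tau / 1 - Tau).
`rescale_bins` removes covariate confounding (gene length, species count)
by standardizing scores within covariate-quantile bins (default 10 bins;
the count is not stated in the source; undersized bins merge downward).
Significance: a Kolmogorov-Smirnov check picks between the exact
finite-population normal approximation for a size-m sum without
replacement and an empirical null of random same-size sets (400,000 draws
at full scale, configurable down for tests), drawn from the scored
universe of the same tissue.  One-sided (greater) is the default since
directional scoring already encodes sign.  Category enrichment (essential
pLI > 0.9 strict, HI top/bottom quartiles, young/old, disease, cancer) is
Fisher's exact test run for Up, Down and Both gene lists.  For
selection-intensity enrichment, log k is the default gene score (k is
multiplicative; a raw-k switch exists).

Selection tables (gene, k, P, omega regimes) are inputs produced by the
published codon-model test, never recomputed.  The lifespan partition
that defines long-lived foreground species is an exact one-dimensional
2-medoid clustering: in 1-D the optimal pair is a split of the sorted
values, so a prefix-sum scan with lower-median medoids is exact,
deterministic, and provably identical to the brute-force medoid-pair
search (tested to n = 200).  The 30-year long-lived cutoff is the
documented default.  Classes: positive association with k > 1 is IU,
positive/k < 1 RU, negative/k > 1 ID, negative/k < 1 RD; k = 1 is
unclassified; |log k| >= log 10 flags strong selection -- the
strong-relaxed threshold is taken symmetric on the log scale (k <= 0.1)
because the source's figure legend and text disagree.

# The synthetic world

`simulate_tree` draws a birth-death (or coalescent) ultrametric tree
rescaled to 150 Myr depth, the span of the radiation being emulated.
`simulate_life_history` evolves log AW by BM (tip sd 2 around log 1000 g)
and sets log ML = 1.8 + 0.2 log AW and log FTM = -1.5 + 0.25 log AW plus
BM residuals of tip sd 0.4 with correlation 0.7 -- the allometric slopes
and the tight ML-FTM coupling mirror the empirical mammalian allometry,
and the residual correlation is what makes the two-trait calling rule
meaningful.  `simulate_expression` plants a configurable fraction of
trait-tracking genes (iid/BM/OU residuals), thins each gene's ortholog
set to `presence_rate` with a floor, and adds within-species replicate
noise (2 replicates, sd 0.25 by default -- the source does not describe
replicate variance, so it is an explicit parameter).  `simulate_counts`
converts to negative-binomial fragment counts with library-size and
gene-length effects (Poisson at dispersion 0); `simulate_selection_table`
draws log-normal k coupled to true association direction.  Every
generator is a pure function of (parameters, seed) and serializes a truth
table sufficient to score every downstream caller.

What the generator does *not* emulate: read-level sampling, assembly and
ortholog-calling artifacts, batch structure beyond a label, and
non-stationary trait evolution.  A green recovery test therefore
establishes that the statistical machinery recovers planted signal under
its own model assumptions -- not that the upstream bioinformatics is
sound.

# Numerical choices

* GLS fits whiten through the Cholesky factor; t tests use n - 2 df;
  log-likelihoods are Gaussian ML with profiled variance.
* OU alpha: bounds `c(1e-3, 100)/depth`; at the lower bound the OU
  log-likelihood is within 1e-3 of BM, at the upper bound (evaluated well
  past it) within 1e-3 of OLS.
* The REML imputer parameterizes `R` by its Cholesky factor with log
  diagonal, noise variances on the log scale, Nelder-Mead with a 400-eval
  budget (the conditional means are insensitive to the tail of the
  optimization; the budget is a runtime choice, with `maxit` exposed).
* Missingness injection deletes an exact rounded count of cells (not
  Bernoulli), so the requested proportion is hit deterministically.
* Permutation P values are `(1 + #{>= obs}) / (n_perm + 1)`: never zero,
  ties count against significance.

# Limitations

* **No measurement-error (nugget) term.**  The three residual models are
  OLS/BM/OU by design.  When species means carry within-species noise,
  BM whitening amplifies that noise on short terminal branches (at the
  generator defaults, replicate sd 0.25 is equivalent to ~23 Myr of
  Brownian variance), which fattens the permutation null of the robust
  statistic and drains power from the 0.005 family-wise cutoff.  The
  calibration and recovery acceptance tests therefore run in the
  species-level ("BM residuals") world they describe; analysts with few
  replicates should prefer the OU model (its alpha partially absorbs the
  nugget) or average more replicates.
* Trait permutation ignores phylogeny.  Under the global null with
  correctly specified covariance this is exact (whitened residuals are
  exchangeable), but strong planted signal inflates the permutation
  maxima of *other* genes' statistics, making maxT conservative rather
  than invalid.
* The imputer assumes BM for every trait; strongly OU-like traits would
  be over-smoothed toward relatives.
* Batch correction is out of scope; the pipeline accepts an externally
  corrected matrix and records batch labels for diagnostics only.
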