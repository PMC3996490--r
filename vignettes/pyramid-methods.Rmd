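---
title: "The pyramid analysis: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The pyramid analysis: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pyramidqtl)
```

## The statistical model

Every edge of the pyramid is an ordinary least-squares regression of one
quantity on another plus an optional shared covariate block $W$ (ancestry
principal components, hidden expression factors — always consumed as
input, never computed here):

$$y_i = \beta_0 + \beta_1 x_i + W_i \gamma + \varepsilon_i,
  \qquad \varepsilon_i \sim N(0, \sigma^2).$$

The reported statistic is always the slope $\beta_1$, its standard error,
$t = \beta_1/\mathrm{se}$, and the two-sided p-value from the Student $t$
distribution with $n - k - 2$ residual degrees of freedom ($k$ covariates).
Two-sided p-values are used throughout; directionality enters the analysis
only once, as the explicit negative-slope constraint at stage 3, reflecting
the assumption that miRNA regulatory activity acts predominantly through
down-regulation of targets. SNP genotypes enter as additive minor-allele
dosages (0/1/2); no dominance terms.

The six stages and their default operating point:

| stage | model | threshold |
|---|---|---|
| 1 | trait ~ gene expression | p < 0.05 |
| 2 | trait ~ miRNA expression | p < 0.05 |
| 3 | gene ~ miRNA (no $W$ term) | p < 10⁻⁴ and slope < 0 |
| 4 | gene ~ SNP (eQTL) | p ≤ 10⁻⁴ |
| 5 | miRNA ~ SNP (miRNA-QTL) | p < 0.05 |
| 6 | trait ~ SNP | p ≤ 10⁻⁴ |

The mixed strict/inclusive operators are part of the method's operating
point; for continuous data the distinction is immaterial except at the
vacuous threshold 1.
Stage 3 tests the full Cartesian product of stage-1 genes and stage-2
miRNAs — no target-prediction database restricts the pairs; only the sign
and the p-value do. Stage-6 candidates are the SNPs surviving **both** QTL
scans (stage 4 ∩ stage 5): the design describes strictly sequential
filtering and every final finding ties a SNP to both a gene and a miRNA,
so the intersection is the coherent reading. Whether stage 5 should scan
all SNPs or only stage-4 survivors is a genuinely open choice; both are
supported (`pyramid_config(stage5_snps=)`), the default
scans all SNPs and intersects afterwards, which yields the same stage-6
candidate set.

Final assembly emits every triplet $(S, M, T)$ whose six edges all pass.
It is a pure set-join, tested against brute-force enumeration, ordered
lexicographically for reproducible output.

## The drug-specific phenotype

IC50 in proliferating cell lines is strongly driven by how fast the line
grows. The phenotype is therefore decomposed as growth plus a
drug-specific component: the DSP is the residual of log2 IC50 regressed on
the intrinsic growth rate (iGrowth), fitted per drug. OLS residuals are
exactly orthogonal to the predictor, so $r^2(\mathrm{DSP}, \mathrm{iGrowth})$
is zero to machine precision (observed $\sim 10^{-32}$ at $n = 90$); this
is a structural identity, not an empirical finding, and the test suite
asserts it on every cohort. iGrowth derivation (an upstream mixed-effects
model) is out of scope: it is consumed as an input column. The log2 scale
is never guessed — raw IC50 must be flagged explicitly.

## Numerical contract of the association engine

All scans share one vectorized engine built on centered cross-products
(with covariates, predictor and response are first projected onto the
orthogonal complement of $[1, W]$; Frisch–Waugh–Lovell). Two properties
matter beyond speed:

* **Subset invariance.** Per-pair statistics are assembled only from
  per-row quantities and per-pair dot products accumulated in fixed sample
  order, so computing a pair inside a genome-wide scan or alone gives
  bit-identical results. The permutation machinery depends on this (below).
* **Degenerate inputs.** A predictor that is constant after complete-case
  reduction has an undefined slope; the engine returns a flagged sentinel
  (slope 0, p = 1, se `NA`) instead of raising, so a genome-wide scan never
  dies mid-chromosome. A constant *response* (exact zero-slope fit) also
  reports p = 1. Monomorphic SNPs are removed before any scan by the MAF
  filter, which is mandatory for this reason; its default minimum (0.05)
  is a conventional choice and configurable. Missing values are handled by
  complete-case analysis per individual test (pairwise deletion), the
  simplest defensible contract; no imputation.

Agreement with an independent `lm()`/normal-equations oracle is part of
the acceptance suite (1000 random problems, observed max relative error
$\sim 4 \times 10^{-15}$).

## Permutation-based empirical FDR

Stage thresholds are user-chosen, and stages 1–5 are fitted on the same
samples later tested at stage 6, so nominal stage-6 p-values are not
uniform under the null and a uniform-null FDR procedure would mislead.
Instead the trait vector is permuted across samples — preserving the
genotype/expression correlation structure — and the entire pyramid is
re-run per permutation. The null statistic set of replicate $b$ is the
stage-6 p-values of that replicate's *final assembled* SNPs, and

$$\widehat{\mathrm{FDR}}(t) =
  \frac{\frac{1}{B}\sum_b \#\{p^{(b)} \le t\}}
       {\max(\#\{p^{\mathrm{obs}} \le t\}, 1)} \wedge 1 .$$

This is the standard permutation plug-in estimator; it is documented here
and isolated in `empirical_fdr()` should a different estimator be wanted.
With no observed discovery at $t$ the FDR is reported `NA` rather than 0 —
there is nothing to rate. An optional cumulative-minimum smoothing
(`monotone = TRUE`) enforces monotone non-decreasing estimates and is
flagged in the output.

Two design choices were genuinely open:

* **What to permute.** The DSP values themselves are permuted, not raw
  IC50: re-residualizing a permuted IC50 against unpermuted iGrowth would
  alter the phenotype's relationship to the (unpermuted) omics layers in an
  ambiguous way. Permuting any other trait column works identically by
  naming it as the trait.
* **Replicate RNG.** Each permutation is seeded counter-style from
  `(seed, perm_index)`, so replicate $i$ is reproducible in isolation and
  independent of execution order, and a run of $B$ permutations contains
  the run of the first $B' < B$ as a prefix.

**Caching.** Permuting the trait cannot change trait-free edges: the
stage-3 pair statistics and the stage-4/5 QTL scans are fixed functions of
the omics matrices. They are computed once and subset per replicate; only
stages 1, 2 and 6 (and which cached edges are *eligible*) are recomputed.
Because of the engine's subset invariance this cache is exact — the suite
asserts bit-identity against naive full recomputation, under both the
default and deliberately relaxed thresholds (so that null finals are
frequently non-empty and the assembly path is exercised).

The comparison methods get the same treatment with their own finding
sets: traditional GWAS (all MAF-passing SNPs, no filter) and the
eQTL-filtered analysis (SNPs passing stage 4 against stage-1 genes; no
miRNA layer). Their null sets per replicate are all eligible SNPs'
p-values. Since the eligible set shrinks from GWAS to eQTL-filtered to
pyramid while a true signal survives the filters, the expected null
exceedance count — the FDR numerator — shrinks correspondingly, which is
the mechanism behind the observed FDR ordering.

## The synthetic cohort generator

The generator emulates the *structure* of the real inputs: $n = 90$
samples (the discovery-panel size), 1000 SNPs / 200 genes / 50 miRNAs at
desk scale, Hardy–Weinberg dosages with MAF uniform on (0.05, 0.5)
(planted SNPs on (0.1, 0.4), so the planted genotype is well populated),
and unit-variance Gaussian expression. A planted chain follows the same
linear structure the pyramid assumes, with standardized effects chosen
once from power arithmetic: SNP→miRNA 0.75, miRNA→gene −0.75,
gene→trait −0.5, miRNA→trait +0.5, trait noise sd 0.5, and growth slope
−0.8 on log2 IC50 (faster growth, lower IC50). These imply population
correlations of about 0.62 (SNP–trait) and −0.56 (SNP–gene), comfortably
but not trivially past the 10⁻⁴ stages at $n = 90$; the observed
recovery rate of the full chain is ~95%.

What the generator does **not** emulate: linkage disequilibrium,
population structure, array-style heteroskedastic noise, heavy tails, or
probe-to-gene mapping ambiguity. Passing tests therefore demonstrate
correctness and calibration of the *procedure* under its own model
assumptions — Gaussian-error linear relations — not robustness to the
messiness of real expression data.

Null calibration (all effects zero) is exact, not approximate: with
Gaussian errors the stage p-values are exactly uniform, and the aggregated
retention rates across 200 null cohorts sit within binomial tolerance of
the nominal 0.05 (observed ≈ 0.0496), with zero final triplets in ≥ 95%
of cohorts (observed 100%).

## Problem sizes and runtime

The suites run at the sizes stated above: 200 null-calibration cohorts,
100 recovery cohorts, 50 method-comparison cohorts with 200 permutations
per method (the conventional 1000 permutations are cut to 200 for
desk-scale replication; the estimator is unchanged), and 200 replicates
for the FDR-honesty property. The full test suite completes in a few
minutes on one CPU; `scripts/acceptance.R` likewise.

## Known limitations

* Expression inputs are assumed pre-normalized; no normalization, batch
  correction or probe mapping is performed.
* Hidden-factor and ancestry covariates must be supplied; the package
  never estimates them.
* The stage-5 candidate policy and the permutation unit (raw IC50 vs DSP)
  are genuinely open design points; both choices are explicit,
  configurable and documented above.
* Empirical FDR resolution is bounded by the permutation count: with
  $B$ permutations the smallest nonzero FDR numerator is $1/B$.
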