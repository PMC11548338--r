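---
title: "Methods: structure-aware across-population genomic prediction"
author: "psapgp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure-aware across-population genomic prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A large hybrid population with genotypes and environment-adjusted trait
BLUPs is available; a genetically distinct breeding population must be
predicted from it. Two things go wrong relative to within-population
prediction. First, marker effects estimated in one population transfer
imperfectly when allele frequencies and ancestry composition differ.
Second, population structure can be confounded with the trait: if
ancestry shifts the phenotype (through unmodelled environment, heterotic
background, or polygenic differentiation), a marker model trained in one
population projects that shift incorrectly onto the other. `psapgp`
addresses both: training-set optimization by relationship to the target
population (MeanRel), and population structure as an explicit fixed
effect in the prediction models.

## Models and estimation

Both models are `y = Q beta + Z gamma + e` with an intercept always
present in `Q` (the fixed-effect design is checked for full rank and
errors on collinear columns, which is why simplex-valued covariates drop
one column; see below).

**GBLUP / REML.** With `gamma ~ N(0, I phi^2 / g)` the marginal model is
`y ~ N(Q beta, G phi^2 + I sigma^2)`, `G = Z Z' / g`. The restricted
likelihood is profiled to the single ratio `lambda = sigma^2 / phi^2`:
after one symmetric eigendecomposition `G = U D U'`, each candidate
`lambda` costs only `O(n l^2)`, and `log(lambda)` is optimized by
`stats::optimize` on `[-10, 10]` (tolerance `1e-9`; the same objective is
exposed as `gblupProfile()` so the 1-D surface can be inspected or
grid-checked). Fixed effects are GLS at the optimum; marker effects are
recovered by the ridge backsolve `gamma = Z'(Z Z' + lambda g I)^{-1}
(y - Q beta)`, which makes the marker-effect and relationship-matrix
formulations numerically identical — a property the test suite asserts
at `1e-8` on random instances. Because `G = Z Z'/g` does not have unit
mean diagonal for general allele-frequency spectra, the reported
additive variance is `phi^2 * mean(diag(G))`, i.e. on the phenotype
scale; `heritability()` is `varG / (varG + varE)`. Degenerate inputs
(zero-residual fits) are guarded by flooring the profiled variance at
the smallest positive double before taking logs.

**BayesB / Gibbs.** Each marker effect has the two-component prior: a
point mass at zero (probability `1 - pi`) and a normal slab whose
variance is marker-specific with a scaled-inverse-chi-square prior
(df `nu`, scale `S`) — jointly a scaled-t slab. The single-site Gibbs
sampler draws, per sweep: fixed effects (flat prior), each marker's
inclusion indicator from the marginal likelihood ratio with the effect
integrated out, the effect and its variance, and the residual variance.
Excluded markers draw their variance from the prior, keeping the chain
proper. Defaults — `nIter = 3000`, `burnIn = 500`, `thin = 5`,
`pi = 0.05`, `nu = 5`, and `S` set so the implied prior genetic variance
is half the phenotypic variance (`r2 = 0.5`) — are explicit and
configurable through `bayesbControl()`; a Beta(1,1) update of `pi` is
available behind `updatePi = TRUE` but off by default so the core
sampler stays verifiable. The sampler is compiled and uses R's RNG, so
a fixed seed reproduces every draw bit-for-bit.

## Structure covariates

All three covariate families are estimated on the combined training +
breeding individual set before any split, and the pipeline
(`acrossPopulationRun`, `runGrid`, the `structure` subcommand) enforces
that ordering.

* **PCA**: leading scores of the column-centered (not standardized)
  dosage matrix; centering-only was chosen because dosages already share
  a scale and standardization would up-weight rare alleles. Six
  components by default; a per-component sign convention (largest
  loading positive) removes eigensolver sign ambiguity.
* **PAM one-hot**: kinship is converted to a dissimilarity
  `d(i,j) = max(K) - K(i,j)` (zero self-dissimilarity), so clustering
  and MeanRel share a single kinship estimate; a Euclidean genotype
  distance can be passed instead. The cluster count is chosen by the
  average silhouette width over a candidate range — an algorithmic
  replacement for reading a scree plot, with the scree curve still
  emitted for inspection. PAM itself (BUILD + SWAP) guarantees a local
  optimum under single-medoid swaps; on unstructured data that local
  optimum can occasionally differ from the global two-medoid optimum,
  which is inherent to the algorithm, not to this implementation.
* **Admixture Q-matrix**: the binomial admixture likelihood
  `sum_ij [g_ij log p_ij + (2 - g_ij) log(1 - p_ij)]`,
  `p_ij = sum_k q_ik f_kj`, maximized by EM with per-allele-copy
  responsibilities. EM was chosen over block-relaxation/quasi-Newton
  solvers because it maximizes the same likelihood, is monotone (the
  trace is asserted non-decreasing in the tests), and is simple to
  verify at desk scale. Initialization: Dirichlet(1) rows for Q and
  observed frequencies plus uniform jitter for F, from a seed;
  convergence when the log-likelihood gains less than `1e-4` (absolute)
  or after 2000 iterations; `F` clipped to `[1e-6, 1 - 1e-6]` and Q rows
  renormalized every step. Components are identified only up to
  permutation; `alignQMatrix()` resolves label switching against a
  reference.

Q rows sum to one, and one-hot memberships sum to one, so either family
plus an intercept is rank-deficient; `qmatrixCovariates()` and
`onehotCovariates()` therefore drop the last column whenever the model
carries an intercept (always, here). This is the package's resolution of
an ambiguity the original workflow leaves open.

## Kinship and MeanRel

Kinship is VanRaden method 1, `K = W W' / (2 sum p_j (1 - p_j))` with
`W` the dosage matrix centered by `2 p_j`; frequencies are computed on
the combined individual set so one joint `K` covers both populations.
MeanRel scores are plain row means of the `K12`
(training-by-breeding) block — un-normalized by diagonals, the simpler
of the two readings of the criterion. Selection is either `top_n`
(ties broken by score descending then id ascending, for determinism) or
`mean_cutoff`, keeping scores strictly greater than their mean; strict
inequality makes tie behaviour deterministic.

## The synthetic generator

The generator emulates the statistical skeleton of a two-population
maize-hybrid study: Balding-Nichols founder frequencies
(`f_kj ~ Beta(p(1-c)/c, (1-p)(1-c)/c)` around ancestral
`p ~ U(0.1, 0.9)`), fully homozygous admixed inbred parents
(`q ~ Dirichlet`, genotype `2 * Bernoulli(q'f)`), F1 hybrids by exact
Mendelian inference (a maternal x paternal factorial for the training
population, a sparse diallel for the breeding population), a sparse
additive trait (`nQtl` loci, N(0,1) effects), and an ancestry-linked
intercept shift standardized to `delta` genetic standard deviations —
the structure confounding the covariates are meant to absorb. Residual
variance is set from the realized genetic variance so
`var(g)/var(y) = h2` when `delta = 0`.

Default study conditions, fixed once: five ancestral groups, divergence
0.2, 500 SNPs, 40 x 10 factorial (400 training hybrids), 100
sparse-diallel breeding hybrids from 50 parents, divergent Dirichlet
concentrations `(2,2,2,.5,.5)` vs `(.5,.5,2,2,2)`, 50 QTL, `h2 = 0.5`,
`delta = 1`. These are a desk-scale replica of a design two orders of
magnitude larger (thousands of hybrids, tens of thousands of SNPs).

What the generator does **not** model: linkage disequilibrium (loci are
independent given ancestry), recombination/pedigree structure, and
multi-environment phenotyping (a replicate-environment flag exists for
noise realism, and `hetRate` injects residual parental heterozygosity to
exercise the missing-call/imputation path). Consequently, passing tests
demonstrate correctness of the estimators and the directional value of
structure adjustment under confounding — not LD-driven transfer effects
in real maize data.

## What the checks show — and a known limitation

The test suite verifies the solvers against independent oracles (dense
REML grid vs the 1-D optimizer; marker-effect vs kinship-block
prediction routes; element-wise kinship recomputation; exhaustive
two-medoid search; admixture truth recovery at K = 2) and the method's
central directional property: with confounded two-population data,
adding the generative ancestry proportions as fixed effects improves
across-population accuracy in almost every replicate for both models.

With *estimated* structure the picture is resolution-limited: at 500
independent SNPs the K = 5 EM estimate carries a mean absolute ancestry
error around 0.19, and the resulting covariates gain little or nothing
on average, whereas the true-ancestry covariates gain substantially
(`scripts/acceptance.R` computes both, per run). In the original
application regime — tens of thousands of SNPs — ancestry is estimated
far more precisely, which is where the fixed-effect strategy pays off.
The package reports both quantities so users can see the mechanism and
its estimation bottleneck separately.

Problem sizes used by the automated checks (the package's choice of
desk-scale replicas): 20 random instances at n = 20 for the REML grid
oracle; 50 simulations at n = 500, g = 1000 for heritability recovery;
n = 400, g = 500, 20 QTL for BayesB inclusion recovery; n = 200,
m = 500 for admixture recovery; 50 replicate studies at the default
conditions for the directional property; and the full 1-trait x
2-model x 8-scenario grid on a 300-SNP replica, run twice to confirm
byte-identical determinism.

## Numerical conventions worth knowing

* Dosages are alt-allele counts 0/1/2 (`NA` = missing); centering to the
  model scale happens inside `buildDesign()`, never in storage.
* Hybrid inference sets a cell missing whenever a parent is heterozygous
  or missing (imputation handles it downstream), keeping raw dosages on
  the 0/1/2 lattice.
* Mean imputation is real-valued and neutral under model centering;
  mode imputation breaks ties toward the lower dosage.
* SNP matching across platforms prefers (chromosome, position) with
  ref/alt harmonization (swapped alleles flip dosages `d -> 2 - d`;
  other mismatches are dropped), falling back to SNP ids without
  metadata.
* Prediction always centers new individuals with the *training*
  allele frequencies, frozen in the fit object.
* Every stochastic routine takes an explicit seed and restores the
  caller's RNG state; reruns are byte-identical.
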