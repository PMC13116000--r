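---
title: "Weighted single-step GBLUP association analysis: models and methods"
author: "wssgblup"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted single-step GBLUP association analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the statistics it
implements: the animal model and its relationship matrices, the REML
algorithm, the SNP back-solving and weighting schemes, the window
partition and recurrence logic, and the design decisions taken where more
than one reasonable implementation exists. It states no empirical result
that the test suite does not itself compute.

## The single-trait animal model

The observation vector is modelled as

$$y = X\beta + Za + e, \qquad a \sim N(0, K\sigma^2_a), \qquad
  e \sim N(0, I\sigma^2_e),$$

where the fixed effects are contemporary-group (CG) classes and age in
days as a linear covariate, and $K$ is a relationship matrix: the
pedigree numerator matrix $A$ when only pedigree is available, or the
unified matrix $H$ when a subset of animals is genotyped. The model
assumes a purely additive genetic architecture, one record per animal,
homogeneous residual variance, and CG effects fixed rather than random.

**Design coding.** `buildDesign()` uses the full set of CG indicator
columns with no separate intercept — the CG classes absorb the intercept,
which is the convention of the standard animal-breeding solvers — plus a
centered age column. This makes a constant shift of $y$ land entirely in
the CG solutions (a property the tests assert) and keeps $X$ full rank
without reference-level bookkeeping. An alternative coding (intercept +
dropped first level) spans the same column space and would give identical
breeding values; we prefer the class-means coding because CG solutions
are then directly interpretable as group means.

## Relationship matrices

* $A$ is built by the tabular recursive method with inbreeding
  ($a_{ii} = 1 + F_i$); $A^{-1}$ by Henderson's rules with Mendelian
  sampling variances from Meuwissen–Luo inbreeding, stored sparse.
* $G = MM'/(2\sum_i p_i q_i)$ with $M$ the dosage matrix centered by
  $2p_i$ (VanRaden). Two silent choices had to be made explicit:
  * *Centering frequencies*: observed frequencies in the genotyped set by
    default. When frequencies are computed from the same animals, the
    columns of $M$ sum to zero and $G$ is singular — which is exactly why
    blending exists. All-genotyped test fixtures therefore pass external
    (simulation-true) frequencies when they need an invertible raw $G$.
  * *Missing dosages* are mean-imputed to $2p_i$ before centering, the
    standard VanRaden treatment.
* Blending: $G^* = \alpha G + (1-\alpha)A_{22}$ with $\alpha = 0.95$.
  We read the published "$0.95\,G + 0.05\,A_{22}^{-1}$" recipe as
  blending with $A_{22}$ *before* inversion: mixing a matrix with an
  inverse has no rank-repairing interpretation, whereas the convex
  combination with a positive-definite $A_{22}$ is the standard fix for a
  singular $G$ and is what the surrounding text motivates.
* $H^{-1} = A^{-1} + \begin{bmatrix}0&0\\0&G^{*-1}-A_{22}^{-1}\end{bmatrix}$,
  with no $\tau/\omega$ scaling. Where REML needs $H$ itself, it is
  assembled densely as $H = A + W(G^*-A_{22})W'$ with
  $W = A_{\cdot 2}A_{22}^{-1}$, which the tests verify against numerical
  inversion of $H^{-1}$.

## REML

`remlEstimate()` is an average-information (AI) REML on
$(\sigma^2_a, \sigma^2_e)$. Because each animal contributes one record,
the marginal likelihood depends on $K$ only through its phenotyped block,
so the algorithm works in the eigenbasis of that block: one symmetric
eigendecomposition up front, after which every iteration (likelihood,
scores, traces, AI matrix) costs $O(np^2)$. This is the same AI
algorithm, merely computed in a rotated basis; estimates are invariant to
record order, which the tests check.

Safeguards, since AI-REML is not globally convergent:

* Components are floored at $10^{-8}\,\mathrm{var}(y)$.
* If an AI step proposes a component below the floor, the step is first
  *projected* onto the floor and accepted if the restricted likelihood
  does not decrease — this is what terminates quickly when the true
  $\sigma^2_a$ is zero. Otherwise an EM step (always positive) is taken,
  with step-halving toward the current point so the likelihood is
  monotone across fallback steps.
* Convergence is declared on a relative component change below `tol`
  (default `1e-8`); hitting `maxIter` flags the result instead of
  raising an error.

The standard error of $h^2$ comes from the inverse AI matrix by the delta
method. Variance components are estimated **once** and held fixed across
all weighting iterations.

## SNP back-solving and the weighting schemes

Effects are back-solved from the genotyped animals' breeding values:

$$\hat u = \frac{1}{\sum_j 2p_jq_j} D M' G_w^{-1} \hat a, \qquad
  G_w = \frac{M D M'}{\sum_j 2p_jq_j}.$$

Two printed forms of these equations required interpretation. The
weighted matrix is *divided* by $\sum 2p_jq_j$ (a multiplicative form
would contradict the unweighted $G$'s own scaling and break the
$D = I$ limit), and this is not configurable because any other reading is
incorrect. The quadratic-weight normalisation is implemented as: set
$d_i = \sigma^2_{u,i} = \hat u_i^2\, 2p_iq_i$, then rescale so
$\sum_i 2p_iq_i d_i$ equals $\sum_i 2p_iq_i$ — the constant-variance
constraint that keeps the total genetic variance stable across
iterations. The blended $G_w^*$ (same $\alpha$ as the unweighted run) is
used wherever an inverse is needed, every iteration.

The three schemes:

* **UM** — single pass, $D = I$. SNP variances are
  $\hat u_i^2\, 2p_iq_i$ for every scheme; weights and variances are
  recorded per iteration.
* **QM** — exactly 3 iterations (weights from squared effects are known
  to over-shrink beyond that); iteration 1 is bit-identical to UM.
  A toggle (`qmUseFreq`) chooses $\hat u_i^2 2p_iq_i$ (default, matching
  the variance definition above) or bare $\hat u_i^2$.
* **Non-linear A** —
  $\sigma^2_{u,i} = \frac{\sigma^2_a}{\sum_j 2p_jq_j}
  k^{|\hat u_i|/sd(\hat u) - 2}$, $k \in \{1.125, 1.2, 1.5\}$, up to 10
  iterations, no cap on weights, convergence when
  $\max_i |\Delta\hat u_i| < 10^{-4}$ (the max-norm is the strictest
  reading of "changes in SNP effects"). The absolute value in the
  exponent is required by symmetry of effects even though compact
  notations often omit it; $k = 1$ collapses to UM exactly, a limit the
  tests assert bit-for-bit.

GEBVs and weights are updated each iteration by re-solving the full
mixed-model equations with the rebuilt $H^{-1}$ — not by any
approximation — so the GBLUP↔SNP-BLUP equivalence oracle (ridge
regression with per-SNP variance $\sigma^2_a/\sum 2pq$ on all-genotyped
fixtures) pins down the entire chain to $10^{-6}$.

## Windows, recurrence, annotation, enrichment

Windows are non-overlapping blocks of 20 physically adjacent SNPs within
a chromosome; a trailing block keeps its `< 20` SNPs and is flagged
(`full = FALSE`) rather than dropped, because silently discarding
chromosome ends would bias against telomeric QTL. Window variance is the
sum of member SNP variances; the percentage of AGV uses the REML
$\sigma^2_a$ as denominator, and the 0.5% threshold is inclusive
(`>=`). Recurrence matching is exact on the shared window grid (all
approaches use the same map); detection by ≥ 2 approaches makes a window
a candidate QTL region, ≥ 3 stable. Regions are extended ±500 kb (clipped
at 1) and intersected with GTF gene features as 1-based closed intervals
via GenomicRanges; the tests verify against a brute-force scan.

The segment-count helper uses $M_e = 2N_eL/\log_{10}(2N_eL)$: only the
base-10 logarithm reproduces the reference value (1644 at $N_e = 104$,
$L = 30$ M) from its inputs, so base 10 is the default with the
natural-log form available.

Enrichment is a deliberately local stand-in for online pathway services:
gene sets arrive as GMT files, the test is the upper-tail hypergeometric
(k = 0 reported with $p = 1$), multiplicity is Benjamini–Hochberg, and
the default universe is all genes of the supplied GTF. Term recurrence
across the five approaches is tabulated because the analysis philosophy
prioritises cross-method stability over a single p-value cutoff.

## The simulator: what it emulates and what it does not

`simulateDataset()` produces discrete generations of random monogamous
mating from a founder cohort; gene-drop genotypes with founder allele
frequencies uniform on a configurable range and meioses with
Poisson-distributed crossovers (Haldane, no interference) on each
chromosome; a trait built as CG effect + age slope × age + TBV +
residual, with TBV split between explicit QTL (effects drawn normal,
rescaled so their realised variance is `qtlVarianceFraction` of
$\sigma^2_a$) and a pedigree polygene sampled by Mendelian-sampling
recursion with inbreeding. Phenotypic variance (TBV + residual) is 1, so
$\sigma^2_a = h^2$ in trait units. The defaults describe a desk-scale
population shaped like a moderate beef-cattle evaluation: $h^2 = 0.26$,
64 contemporary groups, roughly half of the phenotyped animals genotyped,
30 chromosomes (the last labelled X but simulated autosomally — dosage
compensation is out of scope), 1 Morgan and 60 SNPs per chromosome, ages
400–640 days.

Not emulated: founder linkage disequilibrium beyond what the pedigree
generates (no reference LD summary was available to calibrate one),
selection or assortative mating, genotyping error beyond uniform
missingness, and sequence-level variation. Passing tests therefore
demonstrate statistical correctness of the estimators under the stated
generative model, not robustness to ascertainment or selection structure
in real chip data.

## Problem sizes and experiment designs used by the tests

The test suite chooses sizes where each check is sharp:

* Parameter recovery: 20 seeds at $h^2 = 0.26$ with 3000 phenotyped
  final-generation animals (1500 founders, 750 matings × 4 offspring),
  pedigree-only REML; the mean estimate must sit within 3 empirical SE of
  the truth.
* Null recovery: 20 seeds at $h^2 = 0$ with 2000 phenotyped animals in
  200 full-sib families of 10. Family size matters here: with families
  of 4 the sampling SD of $\hat h^2$ under the null is ≈ 0.037, so
  estimates above 0.05 are *expected* a few times in 20; families of 10
  bring the SD to ≈ 0.02, making "$\hat h^2 \le 0.05$ in ≥ 19/20" a test
  of the estimator rather than of luck.
* Sensitivity ordering: a fixed oligogenic population (5 QTL carrying
  30% of $\sigma^2_a$, 1000 genotyped and phenotyped animals, 10 × 100
  SNPs, seed 42). All 1000 animals are genotyped so that back-solving has
  the power to separate explicit QTL from pedigree-polygene leakage; at
  a few hundred animals the leakage can outrank the QTL windows under
  quadratic weighting.
* Equivalence and matrix oracles run at 50 × 200 (animals × SNPs) and
  pedigrees up to 200 animals, where dense reference computations are
  exact and instant.

## Known limitations

* The eigendecomposition-based REML holds the phenotyped-block of $K$
  densely; it is intended for desk-scale analyses (up to a few thousand
  phenotyped animals), not national evaluations.
* Single trait, one record per animal; no maternal or permanent
  environmental effects.
* QM and non-linear A weighting amplify whatever the back-solve
  attributes to a region; with few genotyped animals the amplified signal
  can be family structure rather than QTL. The recurrence rule exists
  precisely to guard interpretation against that instability, and the
  package reports per-iteration states so the amplification is
  inspectable.
* The enrichment module tests over-representation only; it does not
  reproduce any specific online pathway database's statistics.
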