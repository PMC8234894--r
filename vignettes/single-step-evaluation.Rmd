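---
title: "Single-step genomic evaluation with iterative SNP weighting"
author: "singlestep package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-step genomic evaluation with iterative SNP weighting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Small, locally managed livestock populations — a few thousand animals in
the pedigree, a few hundred with performance-test phenotypes, genotyping
introduced only in recent cohorts — cannot support the multi-step genomic
evaluations used in large cosmopolitan breeds, which need a sizeable
reference population of genotyped and phenotyped animals. Single-step
GBLUP (ssGBLUP) sidesteps the problem by evaluating genotyped and
non-genotyped animals jointly: the pedigree relationship matrix of the
classical animal model is replaced by a matrix combining pedigree and
genomic relationships, so every phenotype contributes and the genomic
information propagates through the pedigree.

`singlestep` implements the full workflow for this setting: pedigree
relationship algebra, the VanRaden genomic matrix with base tuning and
blending, the single-step H-inverse, sparse mixed-model solvers, the
iteratively weighted variant (WssGBLUP) with nonlinearA SNP shrinkage,
Gibbs samplers for variance components, the LR cross-validation
estimators, and a gene-dropping simulator with known truth so every stage
can be validated without external data.

## The model

All evaluations use the single-trait animal model

$$y = Xb + Za + e, \qquad a \sim N(0,\,K\sigma^2_a), \quad
  e \sim N(0,\, I\sigma^2_e),$$

where $b$ holds the contemporary-group and dam-parity fixed effects
(drop-first dummy coding with an explicit intercept; the choice of
estimability constraint does not affect EBV contrasts, which a test
asserts) and $a$ is the vector of breeding values for *every* pedigree
animal. The kernel $K$ is:

* **PBLUP**: the numerator relationship matrix $A$. Its inverse is built
  directly by Henderson's rules with inbreeding-corrected
  Mendelian-sampling variances; inbreeding comes from the Meuwissen–Luo
  recursion, which traces each animal's ancestor list instead of forming
  the dense $A$ (tractable at $10^4$ animals).
* **ssGBLUP**: the matrix $H$, used only through its inverse
  $$H^{-1} = A^{-1} + \begin{bmatrix} 0 & 0 \\
    0 & (\alpha G + \beta A_{22})^{-1} - A_{22}^{-1} \end{bmatrix},$$
  where $A_{22}$ is the pedigree block of the genotyped animals (obtained
  by Colleau's indirect method without forming $A$) and
  $G = MM'/(2\sum_i p_i(1-p_i))$ is the VanRaden matrix with $M$ the
  dosage matrix centered by twice the current allele frequencies. Before
  blending, $G$ is tuned ($a + bG$) so its mean diagonal and off-diagonal
  match $A_{22}$'s, aligning the genomic and pedigree genetic bases; the
  blend $\alpha = 0.95, \beta = 0.05$ guarantees invertibility.
* **WssGBLUP**: the same with $G_w = MDM'/(2\sum_i p_i(1-p_i))$, $D$ a
  diagonal matrix of per-SNP weights updated iteratively (below).

Henderson's mixed-model equations are assembled sparse and solved by a
sparse Cholesky factorization (sparse LU fallback); the relative residual
of the normal equations is checked against $10^{-8}$.

## The nonlinearA weighting loop

The plain $G$ assumes every SNP explains the same variance, which is
unrealistic for oligogenic traits. The weighted loop is:

1. $t = 1$, $D = I$ (so iteration 1 **is** ssGBLUP, asserted exactly);
2. solve the single-step MME for GEBVs $\hat a$;
3. backsolve SNP effects
   $\hat u = \delta\, D M'(MDM')^{-1} \hat a_{geno}$;
4. compute nonlinearA weights
   $d_i = CT^{\,|\hat u_i|/sd(\hat u) - 2}$, capped at `limit`;
5. normalize the weights so $\mathrm{tr}(D)$ stays equal to the SNP
   count (constant genetic variance across iterations);
6. rebuild $G_w$, re-tune, re-blend, re-assemble $H^{-1}$; repeat.

Numerical choices worth stating:

* **Backsolve scale.** The printed backsolve formula carries a scale
  constant tied to the genetic-base change; we take $\delta = 1$ and note
  that the weights are invariant to any such constant because they depend
  only on $|\hat u_i|/sd(\hat u)$. $MDM'$ is regularized with a ridge of
  $10^{-8}\cdot\overline{\mathrm{diag}}$ whenever there are fewer SNPs
  than genotyped animals or the matrix is ill-conditioned.
* **Cap and floor.** The default cap is $CT^{5-2} = CT^3$ (1.350, 1.424,
  1.953 for $CT$ = 1.105, 1.125, 1.250); weights are also floored at
  `1/limit`, reading "maximum change in SNP variance" as bounding both
  directions. With the default cap the floor can never bind (the smallest
  raw weight is $CT^{-2} > CT^{-3}$); it matters only for tighter custom
  limits.
* **Trace normalization under the cap.** Plain rescaling
  $d \leftarrow d\,\mathrm{tr}(D^{(1)})/\mathrm{tr}(D)$ can push capped
  weights past the bound. `normalizeWeights()` therefore water-fills:
  weights pinned at a bound stay there and the free weights absorb the
  remaining trace, so the exact trace and the bounds hold
  simultaneously at every iteration (both are asserted each iteration).
* **Rebuild policy.** Tuning and blending are redone from scratch at
  every iteration (a `tune` switch can freeze behaviour); re-deriving
  the tuning scalars keeps the weighted $G$ on the pedigree base as the
  weights reshape its scale.
* **Stopping.** Iteration count is fixed (`nIter`), with an optional
  early stop when successive weight vectors correlate above a threshold;
  published practice explores 1–10 iterations and typically reaches an
  accuracy asymptote by the second.
* **Windows.** `windowVariance()` reports the percentage of genomic
  variance explained by *consecutive non-overlapping* blocks of 20
  map-ordered SNPs (never spanning chromosomes), the convention used for
  the Manhattan-style summaries of weighted runs.

## Variance components

`gibbsUnivariate()` is a standard animal-model Gibbs sampler: all
location parameters are drawn jointly from their multivariate-normal full
conditional via a sparse Cholesky factor whose symbolic analysis is
computed once and numerically updated each round; $\sigma^2_a$ comes from
a scaled inverse chi-square full conditional through the quadratic form
$a'K^{-1}a$, $\sigma^2_e$ from the residual sum of squares. Default
priors are flat on both variances ($\nu = -2$, zero scale).
`retainedDraws()` records the bookkeeping
$\lfloor(\text{chain}-\text{burn-in})/\text{thin}\rfloor$; the
long-chain preset 200000/5000/100 retains 1950 draws. The desk-scale
default is 20000/2000/10.

`gibbsMultitrait()` samples $G_0$ (genetic) and $R_0$ (residual)
covariance matrices under $G_0 \otimes A$ and $R_0 \otimes I$ from
inverse-Wishart full conditionals, with all location parameters drawn
jointly. **Prior choice matters here.** At the sample sizes this package
targets (about $10^3$ records) the posterior mean of a genetic
correlation is visibly prior-sensitive: a "diffuse" inverse-Wishart with
small scale matrix concentrates on near-singular $G_0$ and piles
correlations at $\pm 1$, while a diagonal data-scale prior shrinks them
toward zero. The default is therefore the flat prior on each covariance
matrix (inverse-Wishart form with $\nu = -(t+1)$ and zero scale), the
exact multivariate analog of the univariate flat variance prior; with it,
simulated genetic correlations are recovered without systematic bias
within Monte-Carlo error (checked by test). Records must be complete
across traits; trait-wise missingness handling is not implemented.

`posteriorSummary()` computes per-draw heritabilities
$h^2 = \sigma^2_a/(\sigma^2_a + \sigma^2_e)$ and correlations
$r = \mathrm{cov}/\sqrt{v_1 v_2}$, then reports posterior means with 95%
highest-posterior-density intervals (shortest window on the sorted
draws).

## LR cross-validation

`makePartial()` truncates phenotypes by the *birth year* of the recorded
animal (record dates are not modeled); the focal group is the genotyped
animals born after the cut-off — the young selection candidates. With
focal EBVs $\hat u_p$ (partial) and $\hat u_w$ (whole):

* bias $= \bar{\hat u}_p - \bar{\hat u}_w$ (also reported in genetic-SD
  units), expectation 0;
* dispersion $= \mathrm{cov}(\hat u_w,\hat u_p)/\mathrm{var}(\hat u_p)$,
  expectation 1 (below 1 flags over-dispersion);
* accuracy ratio
  $= \mathrm{cov}(\hat u_w,\hat u_p)/
     \sqrt{\mathrm{var}(\hat u_p)\mathrm{var}(\hat u_w)}$;
* reliability
  $= \mathrm{cov}(\hat u_w,\hat u_p)/((1-\bar F)\sigma^2_u)$ with
  $\sigma^2_u$ the whole-data genetic variance and $\bar F$ the mean
  inbreeding of the *focal group* (reliability targets those animals; a
  switch allows the whole-population mean);
* genomic gain: $\rho_{A,G}$ is the correlation between partial-data
  pedigree and genomic EBVs of the focal group,
  $inc = \rho^{-1}_{A,G} - 1$, and
  $inc_{adj} = (\sigma^2_A/\sigma^2_G)\,inc$.

Sample ($n-1$) variances and covariances are used throughout; this only
matters at tiny focal-group sizes and keeps all estimators on one
convention.

## The simulator

The generator emulates the data structure of a small dual-purpose alpine
cattle population under performance testing — the setting the package is
built for — with known truth at every stage:

* discrete generations, sires and dams drawn from the previous cohort
  (uniformly, or truncation-selected on a latent phenotype);
* founder haplotypes drawn per SNP at frequencies uniform on a
  configurable range, descendants by gene dropping with Haldane
  crossovers on a 1 Morgan/chromosome uniform map — simple, but enough
  linkage to make SNP windows and weighting meaningful;
* QTLs are a subset of the emitted panel (optionally hidden for harder
  scenarios); QTL effects are multivariate normal across traits via the
  Cholesky factor of the target genetic correlation matrix, and each
  trait's breeding values are rescaled so the realized genetic variance
  hits the target $h^2$ exactly (phenotypic variance 1);
* a pedigree-only polygenic mode (no genotypes) draws founder breeding
  values from $N(0, \Sigma_g)$ and descendants as parent average plus
  Mendelian sampling with inbreeding-corrected variance — used where gene
  dropping is irrelevant cost (e.g. the PBLUP calibration studies);
* phenotypes add contemporary-group effects (groups nested in birth
  year, SD 0.5) and parity-class effects (4 classes, SD 0.2) to breeding
  value and correlated residuals; records attach to a configurable
  subset (all animals, non-founders, or recent-cohort males mimicking
  performance-tested bulls);
* `performanceTestDataset()` bundles the scaled emulation: at scale 0.25
  about 2100 pedigree animals, ~440 phenotyped males, ~440 genotyped
  concentrated in the three most recent cohorts, three traits (ADG,
  EUROP, DP) with $h^2$ targets 0.335/0.304/0.392 and a 0.981 genetic
  correlation between the two conformation traits.

What the simulator does *not* reproduce: coalescent founder linkage
disequilibrium, mutation, realistic recombination maps, genotyping
error, or imputation noise. Passing tests therefore demonstrate
algorithmic correctness and calibration under a correctly specified
model, not robustness to the quality problems of real genotype data.

## Problem sizes and expectations used by the validation suite

The test suite and the acceptance script rerun the science at desk
scale, chosen so each check is informative yet quick:

* calibration of the LR estimators: 30 replicates of ~1000 animals
  (5 cohorts of 200), $h^2 = 0.35$, PBLUP at the true variance ratio;
  mean standardized bias within $\pm 0.05$, mean dispersion within
  $\pm 0.10$ of 1;
* oracle equivalences at $10^{-6}$–$10^{-10}$: Henderson's sparse
  $A^{-1}$ against the dense tabular $A$; single-step MME solutions
  against GLS with the dense partitioned $H$; iteration 1 of the
  weighted loop against ssGBLUP; $G := A_{22}$ against PBLUP; tuned-G
  means against $A_{22}$'s;
* parameter recovery: 10 univariate chains (n = 1000, $h^2 = 0.35$,
  95% HPD coverage in at least 8) and 5 bivariate chains
  ($r_g = 0.9$ recovered within $\pm 0.1$ on the mean posterior mean);
* model ordering: 12 oligogenic replicates (5 QTLs / 2000 SNPs,
  ~750 animals, recent-cohort genotyping); mean focal accuracy against
  true breeding values must order PBLUP < ssGBLUP ≤ WssGBLUP
  ($CT = 1.25$, iteration 2).

## Known limitations

* No genetic groups / unknown-parent groups; founders are unrelated and
  non-inbred.
* No imputation, chip merging, or parentage verification; genotypes are
  assumed clean and mean-imputation handles residual missingness.
* Single records per animal; no maternal, dominance, or epistatic
  effects.
* The multi-trait sampler requires complete records across traits.
* Dense Cholesky inversion of the blended genomic matrix limits the
  genotyped set to desk scale (a few thousand animals); APY-style
  approximations are out of scope.
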