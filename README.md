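# singlestep

Genetic and genomic evaluation of small livestock populations with the
animal model: pedigree BLUP, single-step genomic BLUP (ssGBLUP), and
iteratively weighted single-step GBLUP (WssGBLUP) with nonlinearA SNP
shrinkage, together with Gibbs-sampling variance-component estimation and
LR-method cross-validation.

## The problem

In a local breed — a few thousand animals in the pedigree, performance-test
phenotypes on a few hundred bulls, genotyping only in recent cohorts —
multi-step genomic evaluation is not viable: there are too few animals that
are both genotyped and phenotyped to form a reference population.
Single-step GBLUP evaluates genotyped and non-genotyped animals jointly by
replacing the inverse pedigree relationship matrix of the classical animal
model

```
y = Xb + Za + e,   a ~ N(0, K sigma2_a),   e ~ N(0, I sigma2_e)
```

with the single-step inverse

```
H^-1 = A^-1 + [ 0   0                                ]
              [ 0   (alpha G + beta A22)^-1 - A22^-1 ]
```

where `A` is the numerator relationship matrix, `A22` its genotyped block,
and `G = MM' / (2 sum p_i(1-p_i))` the VanRaden genomic matrix (tuned so
its mean diagonal and off-diagonal match `A22`'s, then blended with
`alpha = 0.95, beta = 0.05`). The weighted variant replaces `G` by
`G_w = MDM' / (2 sum p_i(1-p_i))`, where the diagonal weights
`d_i = CT^(|u_i|/sd(u) - 2)` are recomputed each iteration from SNP
effects backsolved out of the GEBVs, capped at `CT^(5-2)` by default, and
trace-normalized so total genetic variance is conserved.

Model quality is judged with the LR cross-validation estimators computed on
the young genotyped focal animals from a whole and a birth-year-truncated
dataset: bias (expectation 0), dispersion (slope, expectation 1), accuracy
ratio, reliability, and the adjusted accuracy gain from genomics
`inc_adj = (sigma2_A / sigma2_G) (1/rho_{A,G} - 1)`.

Everything is testable without external data through a gene-dropping
simulator (founder haplotypes, Haldane crossovers, QTL or polygenic traits
with known truth) that emulates the data structure of a small alpine
dual-purpose breed under performance testing.

## Worked example

```r
library(singlestep)

## a scaled synthetic performance-test dataset: ~2100 pedigree animals,
## three traits, genotyping concentrated in recent cohorts
ds <- performanceTestDataset(seed = 1, scale = 0.25, nSnp = 2000)
ds$ped
#> Pedigree: 2100 animals (300 founders), birth years 2010-2016
nrow(ds$phenotypes); nAnimals(ds$genotypes)
#> [1] 449
#> [1] 447

## whole/partial split at the second-to-last cohort: the 231 genotyped
## animals born after 2015 form the focal group
split <- makePartial(ds$phenotypes, ds$ped, animalIds(ds$genotypes), 2015)

## fit PBLUP and ssGBLUP on the partial data at the simulated variances
d <- list(ped = ds$ped, phenotypes = split$partial,
          genotypes = ds$genotypes)
pb <- runModel(d, "ADG", "PBLUP",   sigmaA2 = 0.335, sigmaE2 = 0.665)
ss <- runModel(d, "ADG", "ssGBLUP", sigmaA2 = 0.335, sigmaE2 = 0.665)

## focal accuracy against the simulator's true breeding values: the
## genomic model sees Mendelian sampling the parent average cannot
tbv <- ds$truth$tbv[split$focal, "ADG"]
cor(ebv(pb)[split$focal], tbv)
#> [1] 0.292
cor(ebv(ss)[split$focal], tbv)
#> [1] 0.341

## the weighted loop: iteration 1 IS ssGBLUP, later iterations sharpen
## the genomic matrix around the detected QTL regions
it <- wssgblup(d, "ADG", CT = 1.25, nIter = 2,
               sigmaA2 = 0.335, sigmaE2 = 0.665)
cor(ebv(it[[2]]$solutions)[split$focal], tbv)
#> [1] 0.349
head(windowVariance(it[[2]]$effects, ds$genotypes), 3)
#>   chrom    start      end      mid n_snp    pct_var
#> 1     1   250000  9750000  4750000    20 0.31125574
#> 2     1 10250000 19750000 14750000    20 0.09927858
#> 3     1 20250000 29750000 24750000    20 0.17341279
```

The 100-QTL trait above gives the genomic models a moderate edge; with a
truly oligogenic architecture the gap widens sharply. Averaged over the
12 replicates of the bundled ordering study (`accuracyOrderingStudy()`,
~750 animals, 5 QTLs on 2000 SNPs) the mean focal accuracies are
approximately 0.35 (PBLUP), 0.83 (ssGBLUP) and 0.83–0.84 (WssGBLUP,
CT = 1.25, iteration 2): genomic data recover the Mendelian-sampling
variation that a parent-average pedigree prediction cannot see.

Variance components come from the Gibbs samplers:

```r
des  <- buildDesign(ds$phenotypes, ds$ped, "ADG")
post <- gibbsUnivariate(des, makeAinverse(ds$ped),
                        chain = 20000, burnIn = 2000, thin = 10, seed = 1)
posteriorSummary(post)   # sigma2_a, sigma2_e, h2 with 95% HPD intervals
```

A configuration-driven end-to-end run (simulate or load, fit all methods
on whole and partial data, LR-validate, write a report) is available as
`runPipeline()`; see `?runPipeline` and the vignette.

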