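test_that("simulated pedigrees are reproducible and structurally sound", {
  cfg <- simConfig(seed = 5, nFounders = 2, nGenerations = 1,
                   nPerGeneration = 1, nSnp = 2, nQtl = 1)
  ped <- simulatePedigree(cfg)
  expect_equal(nAnimals(ped), 3)
  ped2 <- simulatePedigree(cfg)
  expect_identical(animalIds(ped), animalIds(ped2))
  expect_identical(ped@sire, ped2@sire)
  # drift: mean inbreeding accumulates over generations (weak, upward)
  incr <- sapply(1:5, function(sd0) {
    cfg <- simConfig(seed = 50 + sd0, nFounders = 40, nGenerations = 5,
                     nPerGeneration = 40, nSnp = 2, nQtl = 1)
    ped <- simulatePedigree(cfg)
    F <- inbreeding(ped)
    gen <- ped@birthYear - cfg$baseYear
    mF <- tapply(F, gen, mean)
    # late-generation mean above early, and a non-negative overall slope
    mean(mF[4:6]) > mean(mF[1:3]) && mF[6] > mF[1]
  })
  expect_true(all(incr))
})

test_that("gene dropping is Mendelian-consistent with sensible founder
           frequencies", {
  cfg <- simConfig(seed = 6, nFounders = 200, nGenerations = 2,
                   nPerGeneration = 150, nSnp = 300, nChromosomes = 3,
                   nQtl = 10, founderMafRange = c(0.5, 0.5),
                   propGenotyped = c(1, 1, 1))
  ped <- simulatePedigree(cfg)
  g <- dropGenotypes(ped, cfg)
  full <- attr(g, "full")
  X <- dosages(full)
  # founder frequencies close to 0.5 (per-SNP binomial noise at 400
  # alleles has SD 0.025, so the typical deviation stays within 0.05)
  founders <- is.na(ped@sire) & is.na(ped@dam)
  dev <- abs(colMeans(X[founders, ]) / 2 - 0.5)
  expect_lt(mean(dev), 0.05)
  expect_lt(max(dev), 0.12)
  # no parent-offspring pair is ever 0 vs 2 at any SNP
  viol <- 0
  for (i in which(!is.na(ped@sire))) {
    viol <- viol + sum(abs(X[i, ] - X[ped@sire[i], ]) == 2 &
                       (X[i, ] == 0 | X[i, ] == 2) &
                       (X[ped@sire[i], ] == 0 | X[ped@sire[i], ] == 2))
  }
  expect_equal(viol, 0)
  # SNPs distribute over chromosomes with deterministic remainder handling
  expect_equal(as.numeric(table(snpMap(full)$chrom)), rep(100, 3))
  cfg2 <- simConfig(seed = 6, nFounders = 4, nGenerations = 1,
                    nPerGeneration = 4, nSnp = 10, nChromosomes = 3,
                    nQtl = 2)
  g2 <- dropGenotypes(simulatePedigree(cfg2), cfg2)
  expect_equal(as.numeric(table(snpMap(attr(g2, "full"))$chrom)),
               c(4, 3, 3))
})

test_that("realized parent-offspring genomic relationship is about 0.5", {
  cfg <- simConfig(seed = 7, nFounders = 150, nGenerations = 2,
                   nPerGeneration = 180, nSnp = 600, nChromosomes = 5,
                   nQtl = 10, propGenotyped = c(1, 1, 1))
  ped <- simulatePedigree(cfg)
  g <- dropGenotypes(ped, cfg)
  G <- relMatrix(vanRadenG(attr(g, "full")))
  pairs <- which(!is.na(ped@sire))
  rel <- mapply(function(i, s) G[i, s], pairs, ped@sire[pairs])
  expect_lt(abs(mean(rel) - 0.5), 0.05)
})

test_that("phenotypes hit their heritability and correlation targets", {
  rg <- matrix(c(1, 0.9, 0.9, 1), 2, 2)
  cfg <- simConfig(seed = 8, nFounders = 400, nGenerations = 4,
                   nPerGeneration = 400, nSnp = 400, nQtl = 80,
                   propGenotyped = rep(1, 5), h2 = c(0.35, 0.35),
                   geneticCorrelations = rg)
  ped <- simulatePedigree(cfg)
  g <- dropGenotypes(ped, cfg)
  sim <- simulatePhenotypes(ped, g, cfg)
  expect_lt(max(abs(sim$truth$realizedH2 - 0.35)), 0.05)
  expect_lt(abs(sim$truth$realizedGeneticCor[1, 2] - 0.9), 0.08)
  # realized genetic share of the non-fixed phenotypic variance near h2
  ph <- sim$phenotypes
  tbv <- sim$truth$tbv[ph$animal, 1]
  env <- ph$trait1 - tbv
  for (f in c("contemporary_group", "parity_class")) {
    env <- env - ave(env, ph[[f]])
  }
  expect_lt(abs(var(tbv) / (var(tbv) + var(env)) - 0.35), 0.05)
  # zero-heritability trait is pure noise around the fixed effects
  cfg0 <- simConfig(seed = 9, nFounders = 50, nGenerations = 2,
                    nPerGeneration = 50, nSnp = 50, nQtl = 5, h2 = 0,
                    propGenotyped = rep(1, 3))
  ped0 <- simulatePedigree(cfg0)
  sim0 <- simulatePhenotypes(ped0, dropGenotypes(ped0, cfg0), cfg0)
  expect_true(all(sim0$truth$tbv == 0))
})

test_that("the bundled performance-test dataset is deterministic and
           matches its published-scale targets", {
  ds <- performanceTestDataset(seed = 3, scale = 0.1, nSnp = 400)
  expect_equal(ds$cfg$h2, c(0.335, 0.304, 0.392))
  expect_equal(ds$cfg$geneticCorrelations[2, 3], 0.981)
  expect_identical(names(ds$phenotypes)[2:4], c("ADG", "EUROP", "DP"))
  # genotyping concentrated in recent cohorts
  by <- ds$ped@birthYear[match(animalIds(ds$genotypes), animalIds(ds$ped))]
  expect_gte(min(by), ds$cfg$baseYear + 4)
  # byte-identical files from the same seed
  ds2 <- performanceTestDataset(seed = 3, scale = 0.1, nSnp = 400)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  writePhenotypes(ds$phenotypes, f1)
  writePhenotypes(ds2$phenotypes, f2)
  expect_identical(readLines(f1), readLines(f2))
  g1 <- withr::local_tempfile(fileext = ".raw")
  g2 <- withr::local_tempfile(fileext = ".raw")
  writeGenotypes(ds$genotypes, g1)
  writeGenotypes(ds2$genotypes, g2)
  expect_identical(readLines(g1), readLines(g2))
})
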