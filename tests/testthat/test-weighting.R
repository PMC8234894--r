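test_that("backsolved effects reproduce the dense formula and solve
           consistent systems exactly", {
  # centering by the current frequencies makes every column of M sum to
  # zero, so a square M is always singular; the algebraic identity is
  # checked on a consistent right-hand side a = M x instead
  set.seed(3)
  X <- matrix(rbinom(12, 2, 0.5), 4, 3)
  g <- GenotypeData(X, ids = letters[1:4])
  M <- centeredDosages(g)
  aHat <- as.numeric(M %*% c(0.5, -1, 0.25))
  u <- snpEffects(backsolveSnpEffects(aHat, g))
  expect_equal(as.numeric(M %*% u), aHat, tolerance = 1e-6)

  # zero EBVs give zero effects
  expect_equal(unname(snpEffects(backsolveSnpEffects(rep(0, 4), g))),
               rep(0, 3))

  # 5 animals x 3 SNPs with weights: dense evaluation of
  # u = D M' (M D M')^-1 a
  set.seed(4)
  X5 <- matrix(rbinom(15, 2, 0.4), 5, 3)
  g5 <- GenotypeData(X5, ids = letters[1:5])
  M5 <- centeredDosages(g5)
  d <- c(0.5, 1, 2)
  a5 <- rnorm(5)
  MDM <- M5 %*% diag(d) %*% t(M5)
  ridge <- 1e-8 * mean(diag(MDM))
  expected <- diag(d) %*% t(M5) %*% solve(MDM + ridge * diag(5), a5)
  got <- snpEffects(backsolveSnpEffects(a5, g5, weights = d))
  expect_equal(unname(got), as.numeric(expected), tolerance = 1e-6)
})

test_that("nonlinearA weights follow the closed form with the printed caps", {
  # |u| = 2 sd -> weight 1; u = 0, CT = 1.25 -> 1.25^-2 = 0.64
  u <- c(0, 1, -1, 2, -2, 10)
  s <- sd(u)
  w <- nonlinearAWeights(u, CT = 1.25)
  expect_equal(w@limit, 1.25^3)
  expect_equal(snpWeights(w),
               pmin(pmax(1.25^(abs(u) / s - 2), 1 / 1.25^3), 1.25^3))
  # |u|/sd can only exceed the cap exponent with enough SNPs (it is
  # bounded by sqrt(n - 1)); one outlier among 100 engages the cap
  wz <- nonlinearAWeights(c(rep(0, 99), 1), CT = 1.25)
  expect_equal(max(snpWeights(wz)), 1.953125)
  # with the default cap CT^3 the floor 1/CT^3 never binds (the smallest
  # possible weight is CT^-2); a tighter custom limit engages it
  expect_equal(snpWeights(nonlinearAWeights(c(0, 4), CT = 1.25,
                                            limit = 1.3))[1], 1 / 1.3)
  expect_error(nonlinearAWeights(u, CT = 0.9), "CT")
  expect_warning(w0 <- nonlinearAWeights(rep(0, 5), CT = 1.25), "zero")
  expect_equal(snpWeights(w0), rep(1, 5))
})

test_that("trace normalization conserves SNP variance under the cap", {
  mk <- function(d, limit = 10) new("SnpWeights", d = d, CT = 1.25,
                                    limit = limit, iteration = 2L,
                                    traceRef = length(d))
  # all weights 2 over 10 SNPs -> all 1
  expect_equal(snpWeights(normalizeWeights(mk(rep(2, 10)))), rep(1, 10))
  # idempotence
  w <- normalizeWeights(mk(runif(20, 0.5, 2)))
  expect_equal(snpWeights(normalizeWeights(w)), snpWeights(w),
               tolerance = 1e-12)
  # random positive weights, length 100: trace exactly 100
  set.seed(6)
  w2 <- normalizeWeights(mk(rexp(100) + 0.01))
  expect_equal(sum(snpWeights(w2)), 100, tolerance = 1e-10)
  # rescaling that would breach the cap pins capped weights at the bound
  d <- c(rep(0.1, 50), rep(1.9, 10))
  w3 <- normalizeWeights(mk(d, limit = 2))
  expect_equal(sum(snpWeights(w3)), 60, tolerance = 1e-8)
  expect_lte(max(snpWeights(w3)), 2 + 1e-10)
})

test_that("weighted single-step iteration 1 is exactly ssGBLUP and the loop
           keeps its invariants", {
  cfg <- simConfig(seed = 23, nFounders = 24, nGenerations = 3,
                   nPerGeneration = 24, nSnp = 150, nQtl = 5,
                   propGenotyped = c(0, 0.4, 0.7, 0.9))
  ped <- simulatePedigree(cfg)
  g <- dropGenotypes(ped, cfg)
  sim <- simulatePhenotypes(ped, g, cfg)
  d <- list(ped = ped, phenotypes = sim$phenotypes, genotypes = g)
  ss <- runModel(d, "trait", "ssGBLUP", sigmaA2 = 0.35, sigmaE2 = 0.65)
  it <- wssgblup(d, "trait", CT = 1.25, nIter = 3, sigmaA2 = 0.35,
                 sigmaE2 = 0.65)
  expect_equal(ebv(it[[1]]$solutions), ebv(ss), tolerance = 1e-10)
  for (t in seq_along(it)) {
    w <- it[[t]]$weights
    expect_lte(max(snpWeights(w)), w@limit + 1e-8)
    expect_equal(sum(snpWeights(w)), nSnp(g), tolerance = 1e-8)
  }
  # genomic EBVs rebuilt from backsolved effects track the GEBVs
  aG <- ebv(it[[1]]$solutions)[animalIds(g)]
  M <- centeredDosages(g)
  rebuilt <- as.numeric(M %*% snpEffects(it[[1]]$effects))
  expect_gt(cor(rebuilt, aG), 0.99)
})

test_that("weights collapse to unity (and EBVs to ssGBLUP) as CT -> 1", {
  cfg <- simConfig(seed = 29, nFounders = 20, nGenerations = 2,
                   nPerGeneration = 20, nSnp = 100, nQtl = 5,
                   propGenotyped = c(0, 0.5, 0.9))
  ped <- simulatePedigree(cfg)
  g <- dropGenotypes(ped, cfg)
  sim <- simulatePhenotypes(ped, g, cfg)
  d <- list(ped = ped, phenotypes = sim$phenotypes, genotypes = g)
  ss <- runModel(d, "trait", "ssGBLUP", sigmaA2 = 0.35, sigmaE2 = 0.65)
  dev <- sapply(c(1.25, 1.05, 1.005), function(ct) {
    it <- wssgblup(d, "trait", CT = ct, nIter = 2, sigmaA2 = 0.35,
                   sigmaE2 = 0.65)
    c(wdev = max(abs(snpWeights(it[[2]]$weights) - 1)),
      edev = max(abs(ebv(it[[2]]$solutions) - ebv(ss))))
  })
  expect_true(all(diff(dev["wdev", ]) < 0))  # ||D - I|| shrinks with CT
  expect_true(all(diff(dev["edev", ]) < 0))
  expect_lt(dev["edev", 3], 0.05 * max(abs(ebv(ss))))
})

test_that("window variance decomposition matches a brute-force oracle", {
  set.seed(12)
  X <- sapply(runif(9, 0.2, 0.5), function(p) rbinom(8, 2, p))
  map <- data.frame(snp_id = sprintf("s%d", 1:9), chrom = 1L,
                    pos = (1:9) * 100)
  g <- GenotypeData(X, map = map, ids = paste0("a", 1:8))
  u <- rnorm(9)
  wv <- windowVariance(u, g, windowSize = 3)
  expect_equal(nrow(wv), 3)
  M <- centeredDosages(g)
  tot <- var(as.numeric(M %*% u))
  for (k in 1:3) {
    ix <- ((k - 1) * 3 + 1):(k * 3)
    expect_equal(wv$pct_var[k],
                 100 * var(as.numeric(M[, ix] %*% u[ix])) / tot,
                 tolerance = 1e-10)
  }
  # a single window holding all SNPs is the total by self-ratio
  expect_equal(windowVariance(u, g, windowSize = 9)$pct_var, 100)
  # all signal in one SNP: its window carries 100%
  u1 <- c(0, 0, 0, 0, 2, 0, 0, 0, 0)
  wv1 <- windowVariance(u1, g, windowSize = 3)
  expect_equal(wv1$pct_var, c(0, 100, 0))
  expect_error(windowVariance(numeric(0), g), "empty|length")
})
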