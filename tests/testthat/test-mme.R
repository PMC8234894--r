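test_that("design matrices follow drop-first coding and record mapping", {
  ped <- Pedigree(c("A", "B", "C", "D"), c("0", "0", "0", "0"),
                  c("0", "0", "0", "0"))
  ph <- data.frame(animal = c("A", "B", "C", "D"), y = 1:4,
                   contemporary_group = c("g1", "g1", "g2", "g2"),
                   parity_class = 1)
  d <- buildDesign(ph, ped, "y")
  expect_equal(ncol(d$X), 2)  # intercept + 1 CG dummy; constant parity drops
  expect_equal(unname(Matrix::rowSums(d$Z)), rep(1, 4))
  expect_equal(unname(Matrix::colSums(d$Z)), rep(1, 4))
  expect_error(buildDesign(rbind(ph, data.frame(animal = "Z", y = 0,
                                                contemporary_group = "g1",
                                                parity_class = 1)),
                           ped, "y"),
               "Z")
})

test_that("paper-scale fixed-effect structure yields 1 + 141 + 3 columns", {
  set.seed(42)
  nrec <- 1691
  ped <- Pedigree(sprintf("a%04d", 1:nrec), "0", "0")
  ph <- data.frame(animal = sprintf("a%04d", 1:nrec), y = rnorm(nrec),
                   contemporary_group = rep_len(sprintf("cg%03d", 1:142),
                                                nrec),
                   parity_class = sample(1:4, nrec, replace = TRUE))
  d <- buildDesign(ph, ped, "y")
  expect_equal(ncol(d$X), 1 + 141 + 3)
})

test_that("MME solutions match closed forms and the GLS oracle", {
  # single animal, one record y = 10, lambda = 1, K = I:
  # [1 1; 1 2] [b; a] = [10; 10] -> b = 10, a = 0
  ped <- Pedigree("A", "0", "0")
  ph <- data.frame(animal = "A", y = 10, contemporary_group = "g",
                   parity_class = 1)
  d <- buildDesign(ph, ped, "y")
  Ainv <- makeAinverse(ped)
  s <- solveMME(d, Ainv, lambda = 1)
  closed <- solve(matrix(c(1, 1, 1, 2), 2), c(10, 10))
  expect_equal(unname(c(fixedSolutions(s)$estimate, ebv(s))), closed,
               tolerance = 1e-10)

  # infinite shrinkage: EBVs vanish, fixed part is OLS
  cfg <- simConfig(seed = 8, nFounders = 30, nGenerations = 2,
                   nPerGeneration = 30, nSnp = 2, nQtl = 1)
  ped <- simulatePedigree(cfg)
  sim <- simulatePhenotypes(ped, NULL, cfg)
  d <- buildDesign(sim$phenotypes, ped, "trait")
  s <- solveMME(d, makeAinverse(ped), lambda = 1e12)
  expect_lt(max(abs(ebv(s))), 1e-6)
  ols <- qr.solve(d$X, d$y)
  expect_equal(unname(fixedSolutions(s)$estimate), unname(ols),
               tolerance = 1e-4)

  # 30-animal pedigree toy vs dense GLS with V = Z A Z' sA2 + I sE2
  cfg <- simConfig(seed = 13, nFounders = 10, nGenerations = 2,
                   nPerGeneration = 10, nSnp = 2, nQtl = 1)
  ped <- simulatePedigree(cfg)
  sim <- simulatePhenotypes(ped, NULL, cfg)
  d <- buildDesign(sim$phenotypes, ped, "trait")
  s <- solveMME(d, makeAinverse(ped), sigmaA2 = 0.35, sigmaE2 = 0.65)
  oracle <- glsOracle(d, tabularOracleA(ped), 0.35, 0.65)
  expect_equal(ebv(s), oracle$a, tolerance = 1e-8)
  expect_equal(unname(fixedSolutions(s)$estimate), oracle$b,
               tolerance = 1e-8)
})

test_that("fixed-effect residual orthogonality holds at the solution", {
  cfg <- simConfig(seed = 21, nFounders = 40, nGenerations = 2,
                   nPerGeneration = 40, nSnp = 2, nQtl = 1)
  ped <- simulatePedigree(cfg)
  sim <- simulatePhenotypes(ped, NULL, cfg)
  d <- buildDesign(sim$phenotypes, ped, "trait")
  s <- solveMME(d, makeAinverse(ped), lambda = 2)
  e <- d$y - d$X %*% fixedSolutions(s)$estimate -
    as.numeric(d$Z %*% ebv(s)[d$animalIds])
  expect_lt(max(abs(crossprod(d$X, e))), 1e-8)
})

test_that("solutions are invariant to animal ordering in the input file", {
  cfg <- simConfig(seed = 31, nFounders = 16, nGenerations = 2,
                   nPerGeneration = 16, nSnp = 2, nQtl = 1)
  ped <- simulatePedigree(cfg)
  sim <- simulatePhenotypes(ped, NULL, cfg)
  d1 <- buildDesign(sim$phenotypes, ped, "trait")
  s1 <- solveMME(d1, makeAinverse(ped), lambda = 2)
  # shuffle the raw pedigree rows and rebuild
  path <- withr::local_tempfile(fileext = ".csv")
  writePedigree(ped, path)
  df <- read.csv(path, colClasses = "character")
  set.seed(1)
  df <- df[sample(nrow(df)), ]
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path2, row.names = FALSE, quote = FALSE)
  ped2 <- readPedigree(path2)
  d2 <- buildDesign(sim$phenotypes, ped2, "trait")
  s2 <- solveMME(d2, makeAinverse(ped2), lambda = 2)
  expect_equal(ebv(s2)[names(ebv(s1))], ebv(s1), tolerance = 1e-8)
})

test_that("ssGBLUP collapses to PBLUP when genomics is vacuous", {
  cfg <- simConfig(seed = 17, nFounders = 20, nGenerations = 3,
                   nPerGeneration = 20, nSnp = 80, nQtl = 8,
                   propGenotyped = c(0, 0.3, 0.5, 0.8))
  ped <- simulatePedigree(cfg)
  g <- dropGenotypes(ped, cfg)
  sim <- simulatePhenotypes(ped, g, cfg)
  d <- list(ped = ped, phenotypes = sim$phenotypes, genotypes = g)
  pb <- runModel(d, "trait", "PBLUP", lambda = 2)
  # route 1: no genotyped animals at all
  d0 <- list(ped = ped, phenotypes = sim$phenotypes, genotypes = NULL)
  des <- buildDesign(sim$phenotypes, ped, "trait")
  h0 <- hInverse(makeAinverse(ped))
  s0 <- solveMME(des, h0, lambda = 2)
  expect_equal(ebv(s0), ebv(pb), tolerance = 1e-10)
  # route 2: G forced equal to A22 -> correction block cancels
  A22 <- makeA(ped, animalIds(g))
  Gb <- new("RelationshipMatrix", kind = "G_BLEND",
            matrix = relMatrix(A22), ids = animalIds(g))
  sEq <- solveMME(des, hInverse(makeAinverse(ped), A22, Gb), lambda = 2)
  expect_equal(ebv(sEq), ebv(pb), tolerance = 1e-8)
})

test_that("run_model validates genomic prerequisites", {
  cfg <- simConfig(seed = 19, nFounders = 10, nGenerations = 1,
                   nPerGeneration = 10, nSnp = 2, nQtl = 1)
  ped <- simulatePedigree(cfg)
  sim <- simulatePhenotypes(ped, NULL, cfg)
  d <- list(ped = ped, phenotypes = sim$phenotypes, genotypes = NULL)
  expect_error(runModel(d, "trait", "ssGBLUP", lambda = 1), "genotypes")
  expect_error(runModel(d, "trait", "WssGBLUP", lambda = 1), "genotypes")
})
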