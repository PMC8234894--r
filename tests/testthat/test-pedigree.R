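test_that("construction sorts parents before offspring and normalizes unknowns", {
  # offspring listed first: sorting must recover parent-first order
  ped <- Pedigree(c("X", "A", "B"), c("A", "0", ""), c("B", "", "0"))
  expect_identical(animalIds(ped)[3], "X")
  expect_true(all(is.na(ped@sire[1:2])))
  ped2 <- Pedigree(c("A", "B", "X"), c("0", "0", "A"), c("0", "0", "B"))
  expect_identical(animalIds(ped), animalIds(ped2))
  expect_identical(ped@sire, ped2@sire)
})

test_that("duplicates, cycles, and absent parents are handled as specified", {
  expect_error(Pedigree(c("A", "A"), c("0", "0"), c("0", "0")), "duplicate")
  expect_error(Pedigree("A", "A", "0"), "cycle")
  # two-node cycle through both parent columns
  expect_error(Pedigree(c("A", "B"), c("B", "A"), c("0", "0")), "cycle")
  expect_warning(ped <- Pedigree("X", "S", "D"), "founder")
  expect_equal(nAnimals(ped), 3)
})

test_that("inbreeding matches the tabular-A diagonal on random pedigrees", {
  # classical identity first: offspring of non-inbred full sibs
  ped <- inbredPedigree()
  F <- inbreeding(ped)
  expect_equal(unname(F[c("A", "B")]), c(0, 0))
  expect_equal(unname(F["E"]), 0.25)
  for (seed in 1:3) {
    rped <- randomPedigree(50, seed = seed)
    expect_equal(unname(inbreeding(rped)),
                 unname(diag(tabularOracleA(rped)) - 1), tolerance = 1e-12)
  }
})

test_that("numerator relationships reproduce the classical values", {
  ped <- inbredPedigree()
  A <- relMatrix(makeA(ped))
  expect_equal(A["A", "C"], 0.5)   # parent-offspring, unrelated mates
  expect_equal(A["C", "D"], 0.5)   # non-inbred full sibs
  expect_equal(A["E", "E"], 1.25)  # diagonal = 1 + F
  expect_equal(A, tabularOracleA(ped), tolerance = 1e-12)
})

test_that("A-inverse from Henderson's rules inverts tabular A, and the
           inbreeding correction is required", {
  for (seed in 1:2) {
    ped <- randomPedigree(60, seed = seed)
    A <- tabularOracleA(ped)
    Ainv <- as.matrix(relMatrix(makeAinverse(ped)))
    expect_lt(max(abs(Ainv %*% A - diag(nrow(A)))), 1e-8)
  }
  # with inbred parents, rules ignoring inbreeding must NOT match
  ped <- inbredPedigree()
  ped2 <- Pedigree(c(animalIds(ped), "Z"), c("0", "0", "A", "A", "C", "E"),
                   c("0", "0", "B", "B", "D", "D"))
  A <- tabularOracleA(ped2)
  Ainv <- as.matrix(relMatrix(makeAinverse(ped2)))
  expect_lt(max(abs(Ainv %*% A - diag(nrow(A)))), 1e-8)
  # naive variant: Mendelian variances without the parental-F correction
  naive <- matrix(0, 6, 6)
  for (i in 1:6) {
    s <- ped2@sire[i]; d <- ped2@dam[i]
    nPar <- sum(!is.na(c(s, d)))
    b <- 1 / c(1, 0.75, 0.5)[nPar + 1]
    naive[i, i] <- naive[i, i] + b
    for (p in c(s, d)[!is.na(c(s, d))]) {
      naive[i, p] <- naive[p, i] <- naive[i, p] - b / 2
      naive[p, p] <- naive[p, p] + b / 4
    }
    if (nPar == 2) {
      naive[s, d] <- naive[d, s] <- naive[s, d] + b / 4
    }
  }
  expect_gt(max(abs(naive %*% A - diag(6))), 1e-3)
})

test_that("single founder gives the 1x1 identity inverse", {
  ped <- Pedigree("A", "0", "0")
  expect_equal(as.matrix(relMatrix(makeAinverse(ped))),
               matrix(1, dimnames = list("A", "A")))
})

test_that("genotyped-subset block A22 equals the tabular submatrix", {
  ped <- randomPedigree(50, seed = 7)
  ids <- sample(animalIds(ped), 10)
  A22 <- makeA22(ped, ids)
  expect_equal(relMatrix(A22$A22), tabularOracleA(ped)[ids, ids],
               tolerance = 1e-12)
  expect_lt(max(abs(as.matrix(relMatrix(A22$A22inv)) %*%
                    relMatrix(A22$A22) - diag(10))), 1e-8)
  # all animals: A22 == A; two unrelated founders: identity
  expect_equal(relMatrix(makeA(ped, animalIds(ped))),
               relMatrix(makeA(ped)))
  two <- Pedigree(c("A", "B"), c("0", "0"), c("0", "0"))
  expect_equal(unname(relMatrix(makeA(two, c("A", "B")))), diag(2))
  expect_error(makeA(ped, character(0)), "empty")
  expect_error(makeA22(ped, rep(ids[1], 2)), "singular|duplicated")
})

test_that("A is positive definite and consistent across routes", {
  ped <- randomPedigree(80, seed = 3)
  A <- relMatrix(makeA(ped))
  expect_gt(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values), 0)
  ids <- sample(animalIds(ped), 8)
  expect_equal(relMatrix(makeA(ped, ids)), A[ids, ids], tolerance = 1e-12)
})

test_that("pedigree CSV round-trips through the reader", {
  ped <- randomPedigree(40, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  writePedigree(ped, path)
  ped2 <- readPedigree(path)
  expect_identical(animalIds(ped2), animalIds(ped))
  expect_identical(ped2@sire, ped@sire)
  expect_identical(ped2@birthYear, ped@birthYear)
})
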