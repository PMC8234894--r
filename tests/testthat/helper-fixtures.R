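# Fixtures built in code: small pedigrees, genotype sets, and dense oracles
# used to cross-check the sparse/recursive implementations.

# founders A, B; full sibs C, D; E their (inbred) offspring
inbredPedigree <- function() {
  Pedigree(c("A", "B", "C", "D", "E"),
           c("0", "0", "A", "A", "C"),
           c("0", "0", "B", "B", "D"),
           birthYear = c(2000, 2000, 2001, 2001, 2002),
           sex = c("M", "F", "M", "F", "M"))
}

# random multi-generation pedigree with known-good structure
randomPedigree <- function(n = 50, seed = 1, generations = 4) {
  per <- ceiling(n / (generations + 1))
  cfg <- simConfig(seed = seed, nFounders = per, nGenerations = generations,
                   nPerGeneration = per, nSnp = 2, nQtl = 1)
  simulatePedigree(cfg)
}

# dense numerator relationship by the plain tabular recursion, written
# independently of makeA()
tabularOracleA <- function(ped) {
  n <- nAnimals(ped)
  s <- ped@sire
  d <- ped@dam
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1)) {
      aij <- 0
      if (!is.na(s[i])) aij <- aij + 0.5 * A[j, s[i]]
      if (!is.na(d[i])) aij <- aij + 0.5 * A[j, d[i]]
      A[i, j] <- A[j, i] <- aij
    }
    A[i, i] <- 1 + if (!is.na(s[i]) && !is.na(d[i])) 0.5 * A[s[i], d[i]]
                   else 0
  }
  dimnames(A) <- list(animalIds(ped), animalIds(ped))
  A
}

# small genotype set with map, optionally with missing values
toyGenotypes <- function(seed = 1, n = 12, m = 30, missing = 0) {
  set.seed(seed)
  p <- runif(m, 0.1, 0.5)
  X <- sapply(p, function(pp) rbinom(n, 2, pp))
  if (missing > 0) X[sample(length(X), missing)] <- NA
  map <- data.frame(snp_id = sprintf("s%03d", 1:m),
                    chrom = rep(1:3, length.out = m),
                    pos = rep(seq_len(ceiling(m / 3)) * 1000,
                              times = 3)[1:m])
  GenotypeData(X, map = map, ids = sprintf("an%02d", 1:n))
}

# dense H from the partitioned identity: genotyped block replaced by Gb,
# non-genotyped block adjusted through A12 A22^-1
denseHOracle <- function(ped, genotypedIds, Gb) {
  A <- tabularOracleA(ped)
  ids <- animalIds(ped)
  g <- match(genotypedIds, ids)
  f <- setdiff(seq_along(ids), g)
  A22i <- solve(A[g, g])
  H <- A
  H[g, g] <- Gb
  H[f, g] <- A[f, g] %*% A22i %*% Gb
  H[g, f] <- t(H[f, g])
  H[f, f] <- A[f, f] + A[f, g] %*% A22i %*% (Gb - A[g, g]) %*% A22i %*%
    A[g, f]
  H
}

# GLS / selection-index oracle for the animal model with dense kernel K:
# bhat = (X' V^-1 X)^-1 X' V^-1 y,  ahat = sA2 K Z' V^-1 (y - X bhat)
glsOracle <- function(design, K, sigmaA2, sigmaE2) {
  X <- design$X
  Z <- as.matrix(design$Z)
  y <- design$y
  V <- sigmaA2 * Z %*% K %*% t(Z) + sigmaE2 * diag(length(y))
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  a <- sigmaA2 * K %*% t(Z) %*% Vi %*% (y - X %*% b)
  list(b = as.numeric(b), a = setNames(as.numeric(a), design$animalIds))
}
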