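test_that("chain bookkeeping retains floor((chain - burnIn)/thin) draws", {
  expect_equal(retainedDraws(200000, 5000, 100), 1950L)
  cfg <- simConfig(seed = 61, nFounders = 40, nGenerations = 2,
                   nPerGeneration = 40, nSnp = 2, nQtl = 1)
  ped <- simulatePedigree(cfg)
  sim <- simulatePhenotypes(ped, NULL, cfg)
  d <- buildDesign(sim$phenotypes, ped, "trait")
  post <- gibbsUnivariate(d, makeAinverse(ped), chain = 230, burnIn = 30,
                          thin = 7, seed = 2)
  expect_equal(nrow(post@draws), retainedDraws(230, 30, 7))
  expect_false(anyNA(post@draws))
})

test_that("chains are deterministic given the seed", {
  cfg <- simConfig(seed = 62, nFounders = 30, nGenerations = 2,
                   nPerGeneration = 30, nSnp = 2, nQtl = 1)
  ped <- simulatePedigree(cfg)
  sim <- simulatePhenotypes(ped, NULL, cfg)
  d <- buildDesign(sim$phenotypes, ped, "trait")
  Ainv <- makeAinverse(ped)
  p1 <- gibbsUnivariate(d, Ainv, chain = 200, burnIn = 50, thin = 2,
                        seed = 9)
  p2 <- gibbsUnivariate(d, Ainv, chain = 200, burnIn = 50, thin = 2,
                        seed = 9)
  expect_identical(p1@draws, p2@draws)
})

test_that("pure-noise data concentrate the heritability posterior near 0", {
  set.seed(4)
  ped <- Pedigree(sprintf("a%03d", 1:500),
                  c(rep("0", 100), sprintf("a%03d", sample(50, 400,
                                                           TRUE))),
                  c(rep("0", 100), sprintf("a%03d", sample(51:100, 400,
                                                           TRUE))))
  ph <- data.frame(animal = animalIds(ped), y = rnorm(500),
                   contemporary_group = sample(sprintf("g%d", 1:10), 500,
                                               replace = TRUE),
                   parity_class = sample(1:4, 500, replace = TRUE))
  d <- buildDesign(ph, ped, "y")
  post <- gibbsUnivariate(d, makeAinverse(ped), chain = 1500, burnIn = 300,
                          thin = 2, seed = 3)
  sm <- posteriorSummary(post)
  expect_lt(sm$mean[sm$parameter == "h2"], 0.15)
})

test_that("with an identity kernel the sampler agrees with the one-way
           ANOVA variance decomposition", {
  # balanced sire-family layout: between-family variance = sigma2_a / ...
  # use repeated records per 'animal' with K = I so the posterior for the
  # two components matches the classical ANOVA estimates
  set.seed(8)
  q <- 40; rep <- 8
  u <- rnorm(q, 0, sqrt(0.5))
  y <- rep(u, each = rep) + rnorm(q * rep, 0, 1)
  ped <- Pedigree(sprintf("s%02d", 1:q), "0", "0")
  ph <- data.frame(animal = rep(sprintf("s%02d", 1:q), each = rep), y = y,
                   contemporary_group = "g", parity_class = 1)
  d <- buildDesign(ph, ped, "y")
  Ident <- new("RelationshipMatrix", kind = "A_INV",
               matrix = Matrix::Diagonal(q), ids = animalIds(ped))
  post <- gibbsUnivariate(d, Ident, chain = 3000, burnIn = 500, thin = 2,
                          seed = 5)
  sm <- posteriorSummary(post)
  fit <- anova(lm(y ~ factor(rep(1:q, each = rep))))
  msb <- fit$`Mean Sq`[1]; msw <- fit$`Mean Sq`[2]
  anovaA <- (msb - msw) / rep
  expect_lt(abs(sm$mean[sm$parameter == "sigma2_a"] - anovaA),
            3 * sqrt(2 / q) * anovaA)
  expect_lt(abs(sm$mean[sm$parameter == "sigma2_e"] - msw), 0.15 * msw)
})

test_that("a duplicated trait drives the genetic correlation to one", {
  cfg <- simConfig(seed = 63, nFounders = 80, nGenerations = 3,
                   nPerGeneration = 80, nSnp = 2, nQtl = 1, h2 = 0.4)
  ped <- simulatePedigree(cfg)
  sim <- simulatePhenotypes(ped, NULL, cfg)
  ph <- sim$phenotypes
  # same true breeding values, independent measurement noise on the copy
  ph$copy <- ph$trait + rnorm(nrow(ph), 0, 0.3)
  post <- gibbsMultitrait(ph, ped, c("trait", "copy"), chain = 600,
                          burnIn = 100, thin = 2, seed = 7)
  sm <- posteriorSummary(post)
  expect_gt(sm$mean[sm$parameter == "rg_trait_copy"], 0.95)
  expect_error(gibbsMultitrait(ph, ped, "trait"), "2 traits")
})

test_that("posterior summaries and HPD intervals follow their definitions", {
  mk <- function(m) new("PosteriorSamples",
                        draws = m, traits = "t", chain = nrow(m),
                        burnIn = 0, thin = 1, seed = 1)
  const <- mk(cbind(sigma2_a = rep(2, 50), sigma2_e = rep(2, 50)))
  sm <- posteriorSummary(const)
  expect_equal(sm$mean[sm$parameter == "sigma2_a"], 2)
  expect_equal(sm$lower[1], sm$upper[1])
  expect_equal(sm$mean[sm$parameter == "h2"], 0.5)
  # uniform draws 1..100: shortest 95% window spans 94
  hpd <- hpdInterval(1:100, 0.95)
  expect_equal(hpd[2] - hpd[1], 94)
  expect_error(posteriorSummary(mk(cbind(sigma2_a = rep(1, 10),
                                         sigma2_e = rep(1, 10)))),
               "too few")
})
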