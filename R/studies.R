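## Replicated simulation studies: LR calibration under no selection, and
## the accuracy ordering of pedigree vs genomic vs weighted-genomic models.

#' LR calibration under random mating
#'
#' Simulates replicates of an unselected, random-mating population
#' (5 cohorts of equal size, polygenic trait, contemporary-group and parity
#' effects), analyses each with a correctly specified pedigree animal model
#' at the true variance ratio on the whole data and on data truncated
#' before the last cohort, and computes the LR statistics over the
#' last-cohort focal animals. With the model matching the simulation the
#' expected dispersion is 1 and the expected standardized bias 0; the
#' replicate means estimate how well the estimators are calibrated.
#'
#' @param nReplicates number of simulated replicates (default 30).
#' @param seed master seed; replicate r uses `seed + 1000 * r`.
#' @param nFounders,nPerGeneration cohort sizes (default 200 and 200, about
#'   1000 animals over 5 cohorts).
#' @param nGenerations offspring generations (default 4).
#' @param h2 trait heritability (default 0.35; phenotypic variance 1).
#' @return data.frame with one row per replicate (`bias`, `bias_std`,
#'   `dispersion`, `acc`, `n_focal`); replicate means in
#'   `attr(, "means")`.
#' @export
lrCalibrationStudy <- function(nReplicates = 30, seed = 1, nFounders = 200,
                               nPerGeneration = 200, nGenerations = 4,
                               h2 = 0.35) {
  rows <- vector("list", nReplicates)
  for (r in seq_len(nReplicates)) {
    cfg <- simConfig(seed = seed + 1000 * r, nFounders = nFounders,
                     nGenerations = nGenerations,
                     nPerGeneration = nPerGeneration, h2 = h2,
                     nSnp = 2, nQtl = 1, nContempGroups = 20)
    ped <- simulatePedigree(cfg)
    sim <- simulatePhenotypes(ped, NULL, cfg)
    cutoff <- cfg$baseYear + nGenerations - 1
    split <- makePartial(sim$phenotypes, ped, animalIds(ped), cutoff)
    Ainv <- makeAinverse(ped)
    lam <- (1 - h2) / h2
    dW <- buildDesign(sim$phenotypes, ped, cfg$traitNames[1])
    dP <- buildDesign(split$partial, ped, cfg$traitNames[1])
    sW <- solveMME(dW, Ainv, lambda = lam, modelTag = "PBLUP",
                   datasetTag = "WHOLE")
    sP <- solveMME(dP, Ainv, lambda = lam, modelTag = "PBLUP",
                   datasetTag = "PARTIAL")
    st <- lrStatistics(ebv(sP)[split$focal], ebv(sW)[split$focal],
                       sigmaA = sqrt(h2))
    rows[[r]] <- data.frame(replicate = r, bias = st$bias,
                            bias_std = st$bias_std,
                            dispersion = st$dispersion, acc = st$acc,
                            n_focal = st$n_focal)
  }
  out <- do.call(rbind, rows)
  attr(out, "means") <- colMeans(out[, c("bias", "bias_std", "dispersion",
                                         "acc")])
  out
}

#' Accuracy ordering of PBLUP, ssGBLUP, and weighted ssGBLUP
#'
#' Simulates an oligogenic trait (few QTLs on a genome-wide panel) in a
#' multi-generation population with genotyping concentrated in the recent
#' cohorts, fits the three models on data truncated before the youngest
#' cohort, and measures each model's focal-group accuracy as the
#' correlation between its EBVs and the TRUE breeding values of the young
#' genotyped animals. Genomic information captures Mendelian sampling that
#' the parent-average pedigree prediction cannot, and concentrating SNP
#' variance on the QTL regions can add a further margin.
#'
#' @param nSeeds number of replicates (default 12).
#' @param seed master seed; replicate r uses `seed + 1000 * r`.
#' @param nQtl,nSnp genetic architecture (default 5 QTLs on 2000 SNPs).
#' @param CT,nIter weighting parameters (default 1.25, 2 iterations).
#' @param nFounders,nPerGeneration,nGenerations population sizes (default
#'   150/150/4, about 750 animals).
#' @param h2 heritability (default 0.35).
#' @return data.frame with one row per replicate and per-model focal
#'   accuracies (`acc_pblup`, `acc_ssgblup`, `acc_wssgblup`); means in
#'   `attr(, "means")`.
#' @export
accuracyOrderingStudy <- function(nSeeds = 12, seed = 1, nQtl = 5,
                                  nSnp = 2000, CT = 1.25, nIter = 2,
                                  nFounders = 150, nPerGeneration = 150,
                                  nGenerations = 4, h2 = 0.35) {
  rows <- vector("list", nSeeds)
  for (r in seq_len(nSeeds)) {
    cfg <- simConfig(seed = seed + 1000 * r, nFounders = nFounders,
                     nGenerations = nGenerations,
                     nPerGeneration = nPerGeneration, h2 = h2,
                     nSnp = nSnp, nChromosomes = 10, nQtl = nQtl,
                     propGenotyped = c(rep(0, nGenerations - 2),
                                       0.5, 0.9, 0.9),
                     nContempGroups = 15)
    ped <- simulatePedigree(cfg)
    g <- dropGenotypes(ped, cfg)
    sim <- simulatePhenotypes(ped, g, cfg)
    cutoff <- cfg$baseYear + nGenerations - 1
    split <- makePartial(sim$phenotypes, ped, animalIds(g), cutoff)
    tbv <- sim$truth$tbv[split$focal, 1]
    d <- list(ped = ped, phenotypes = split$partial, genotypes = g)
    sP <- runModel(d, cfg$traitNames[1], "PBLUP", sigmaA2 = h2,
                   sigmaE2 = 1 - h2)
    sS <- runModel(d, cfg$traitNames[1], "ssGBLUP", sigmaA2 = h2,
                   sigmaE2 = 1 - h2)
    itW <- wssgblup(d, cfg$traitNames[1], CT = CT, nIter = nIter,
                    sigmaA2 = h2, sigmaE2 = 1 - h2)
    sWg <- itW[[length(itW)]]$solutions
    rows[[r]] <- data.frame(
      replicate = r, n_focal = length(split$focal),
      acc_pblup = stats::cor(ebv(sP)[split$focal], tbv),
      acc_ssgblup = stats::cor(ebv(sS)[split$focal], tbv),
      acc_wssgblup = stats::cor(ebv(sWg)[split$focal], tbv))
  }
  out <- do.call(rbind, rows)
  attr(out, "means") <- colMeans(out[, c("acc_pblup", "acc_ssgblup",
                                         "acc_wssgblup")])
  out
}
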