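## Gene-dropping simulator: pedigree, genotypes, correlated traits with
## known truth. Emulates the data structure of a small dual-purpose alpine
## cattle population: multi-generation pedigree, genotyping concentrated in
## recent cohorts, performance-test phenotypes with contemporary-group and
## parity fixed effects.

#' Simulation recipe
#'
#' Assembles and validates the full recipe for one synthetic dataset. All
#' downstream generators are deterministic given `seed` (genotype dropping
#' uses `seed + 1`, phenotypes `seed + 2`, so the pieces are reproducible
#' independently of call order).
#'
#' @param seed integer master seed.
#' @param nFounders founder animals (generation 0, half of each sex).
#' @param nGenerations number of discrete offspring generations.
#' @param nPerGeneration offspring born per generation.
#' @param offspringPerMating full sibs per mating.
#' @param propGenotyped per-generation genotyped fractions (length
#'   `nGenerations + 1`, generation 0 first). Default: none genotyped.
#' @param nSnp,nChromosomes marker panel; SNPs are spread evenly with the
#'   remainder given to the first chromosomes, 1 Morgan per chromosome.
#' @param founderMafRange (low, high) of the founder counted-allele
#'   frequency, drawn uniformly per SNP.
#' @param nQtl number of QTLs (a subset of the emitted SNPs unless
#'   `hideQtl`).
#' @param hideQtl drop the QTL columns from the emitted panel (harder
#'   scenario).
#' @param h2 per-trait heritability targets in (0, 1) (phenotypic variance
#'   is 1, so h2 is also the genetic variance).
#' @param traitNames trait column names.
#' @param geneticCorrelations,residualCorrelations trait correlation
#'   matrices (positive definite).
#' @param nContempGroups approximate number of contemporary-group levels
#'   over the whole dataset (groups are nested in birth year).
#' @param nParityClasses number of dam-parity classes.
#' @param sdCG,sdParity SD of the contemporary-group and parity effects
#'   (trait units).
#' @param phenotyped list: `rule` one of `"all"`, `"males"`,
#'   `"nonfounders"`; `fromGeneration` first phenotyped generation.
#' @param selection list: `type` `"NONE"` or `"TRUNCATION"`, `fraction` the
#'   top fraction (on a latent phenotype of heritability `h2[1]`) eligible
#'   as parents.
#' @param baseYear calendar year of generation 0.
#' @return validated list of class `simConfig`.
#' @export
simConfig <- function(seed = 1, nFounders = 100, nGenerations = 4,
                      nPerGeneration = nFounders, offspringPerMating = 2,
                      propGenotyped = NULL, nSnp = 1000, nChromosomes = 5,
                      founderMafRange = c(0.05, 0.5), nQtl = 50,
                      hideQtl = FALSE, h2 = 0.35, traitNames = NULL,
                      geneticCorrelations = NULL,
                      residualCorrelations = NULL, nContempGroups = 20,
                      nParityClasses = 4, sdCG = 0.5, sdParity = 0.2,
                      phenotyped = list(rule = "all", fromGeneration = 0),
                      selection = list(type = "NONE", fraction = 0.5),
                      baseYear = 2000) {
  nTraits <- length(h2)
  if (is.null(traitNames)) {
    traitNames <- if (nTraits == 1) "trait" else
      paste0("trait", seq_len(nTraits))
  }
  if (is.null(geneticCorrelations)) geneticCorrelations <- diag(nTraits)
  if (is.null(residualCorrelations)) residualCorrelations <- diag(nTraits)
  if (is.null(propGenotyped)) propGenotyped <- rep(0, nGenerations + 1)
  stopifnot(all(h2 >= 0), all(h2 < 1), nQtl <= nSnp,
            length(propGenotyped) == nGenerations + 1,
            all(propGenotyped >= 0), all(propGenotyped <= 1),
            founderMafRange[1] > 0, founderMafRange[2] <= 0.5,
            length(traitNames) == nTraits)
  for (nm in c("geneticCorrelations", "residualCorrelations")) {
    R <- get(nm)
    if (!all(dim(R) == nTraits) ||
        min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
      stop(nm, " must be a positive-definite ", nTraits, "x", nTraits,
           " matrix")
    }
  }
  if (!selection$type %in% c("NONE", "TRUNCATION")) {
    stop("selection$type must be NONE or TRUNCATION")
  }
  structure(list(
    seed = seed, nFounders = nFounders, nGenerations = nGenerations,
    nPerGeneration = nPerGeneration,
    offspringPerMating = offspringPerMating,
    propGenotyped = propGenotyped, nSnp = nSnp,
    nChromosomes = nChromosomes, founderMafRange = founderMafRange,
    nQtl = nQtl, hideQtl = hideQtl, h2 = h2, nTraits = nTraits,
    traitNames = traitNames, geneticCorrelations = geneticCorrelations,
    residualCorrelations = residualCorrelations,
    nContempGroups = nContempGroups, nParityClasses = nParityClasses,
    sdCG = sdCG, sdParity = sdParity, phenotyped = phenotyped,
    selection = selection, baseYear = baseYear), class = "simConfig")
}

#' Simulate a discrete-generation pedigree
#'
#' Generation 0 holds the founders (alternating sexes); each later
#' generation draws sires and dams from the previous one (uniformly, or the
#' top fraction on a latent phenotype under truncation selection) and
#' produces full-sib families of `offspringPerMating`. Birth year =
#' `baseYear` + generation. Reproducible by `cfg$seed`.
#'
#' @param cfg a [simConfig()].
#' @return A [Pedigree-class]; under selection, the latent breeding values
#'   used for ranking are attached as `attr(, "latentBV")`.
#' @export
simulatePedigree <- function(cfg) {
  set.seed(cfg$seed)
  sel <- cfg$selection$type == "TRUNCATION"
  h2 <- cfg$h2[1]
  id <- sprintf("G0_%04d", seq_len(cfg$nFounders))
  sire <- dam <- rep(NA_character_, cfg$nFounders)
  sex <- rep(c("M", "F"), length.out = cfg$nFounders)
  year <- rep(cfg$baseYear, cfg$nFounders)
  bv <- stats::rnorm(cfg$nFounders, 0, sqrt(h2))
  phen <- bv + stats::rnorm(cfg$nFounders, 0, sqrt(1 - h2))
  prev <- seq_len(cfg$nFounders)
  for (g in seq_len(cfg$nGenerations)) {
    candM <- prev[sex[prev] == "M"]
    candF <- prev[sex[prev] == "F"]
    if (sel) {
      keepM <- max(1, floor(length(candM) * cfg$selection$fraction))
      keepF <- max(1, floor(length(candF) * cfg$selection$fraction))
      candM <- candM[order(phen[candM], decreasing = TRUE)[seq_len(keepM)]]
      candF <- candF[order(phen[candF], decreasing = TRUE)[seq_len(keepF)]]
    }
    if (length(candM) == 0 || length(candF) == 0) {
      stop("population extinct at generation ", g,
           ": no selectable ", if (length(candM) == 0) "sires" else "dams")
    }
    nMat <- ceiling(cfg$nPerGeneration / cfg$offspringPerMating)
    s <- candM[sample.int(length(candM), nMat, replace = TRUE)]
    d <- candF[sample.int(length(candF), nMat, replace = TRUE)]
    s <- rep(s, each = cfg$offspringPerMating)[seq_len(cfg$nPerGeneration)]
    d <- rep(d, each = cfg$offspringPerMating)[seq_len(cfg$nPerGeneration)]
    newIdx <- length(id) + seq_len(cfg$nPerGeneration)
    id <- c(id, sprintf("G%d_%04d", g, seq_len(cfg$nPerGeneration)))
    sire <- c(sire, id[s])
    dam <- c(dam, id[d])
    sex <- c(sex, sample(c("M", "F"), cfg$nPerGeneration, replace = TRUE))
    year <- c(year, rep(cfg$baseYear + g, cfg$nPerGeneration))
    msd <- sqrt(0.5 * h2)
    newBv <- 0.5 * (bv[s] + bv[d]) +
      stats::rnorm(cfg$nPerGeneration, 0, msd)
    bv <- c(bv, newBv)
    phen <- c(phen, newBv + stats::rnorm(cfg$nPerGeneration, 0,
                                         sqrt(1 - h2)))
    prev <- newIdx
  }
  ped <- Pedigree(id, ifelse(is.na(sire), "0", sire),
                  ifelse(is.na(dam), "0", dam), birthYear = year, sex = sex)
  if (sel) {
    attr(ped, "latentBV") <- stats::setNames(bv, id)[animalIds(ped)]
  }
  ped
}

## forward simulation of polygenic breeding values down a sorted pedigree:
## founders ~ MVN(0, Sigma), offspring = parent average + Mendelian
## sampling scaled by ms (inbreeding-corrected variance multiplier)
.polygenicTBV <- function(ped, Sigma, ms) {
  n <- nAnimals(ped)
  nt <- nrow(Sigma)
  L <- chol(Sigma + diag(1e-12, nt))
  E <- matrix(stats::rnorm(n * nt), n, nt) %*% L
  tbv <- matrix(0, n, nt)
  for (i in seq_len(n)) {
    s <- ped@sire[i]
    d <- ped@dam[i]
    pa <- numeric(nt)
    if (!is.na(s)) pa <- pa + 0.5 * tbv[s, ]
    if (!is.na(d)) pa <- pa + 0.5 * tbv[d, ]
    tbv[i, ] <- pa + sqrt(ms[i]) * E[i, ]
  }
  tbv
}

## one gamete from a parent's two chromosome-wise haplotype segments
.gamete <- function(h1, h2, chromIndex, posM) {
  out <- integer(length(h1))
  for (cc in unique(chromIndex)) {
    ix <- which(chromIndex == cc)
    k <- stats::rpois(1, 1)               # Haldane, 1 Morgan
    phase <- rep(sample(0:1, 1), length(ix))
    if (k > 0) {
      xo <- sort(stats::runif(k))
      phase <- (phase + findInterval(posM[ix], xo)) %% 2
    }
    out[ix] <- ifelse(phase == 0L, h1[ix], h2[ix])
  }
  out
}

#' Drop genotypes through a pedigree
#'
#' Founder haplotypes are drawn per SNP from Bernoulli(p) with
#' `p ~ Uniform(founderMafRange)`; descendants inherit recombinant gametes
#' (Haldane crossovers, 1 Morgan per chromosome, SNPs evenly spaced). Only
#' animals flagged genotyped by the per-generation cohort fractions are
#' emitted, mimicking recent-cohort genotyping; the complete matrix over all
#' animals is attached as `attr(, "full")` so trait simulation can use the
#' true genotypes.
#'
#' @param ped a [Pedigree-class] from [simulatePedigree()].
#' @param cfg the same [simConfig()].
#' @return A [GenotypeData-class] of the genotyped animals, with attributes
#'   `full` (all animals) and `qtlCandidates` (column indexes available as
#'   QTLs).
#' @export
dropGenotypes <- function(ped, cfg) {
  set.seed(cfg$seed + 1)
  n <- nAnimals(ped)
  m <- cfg$nSnp
  perChrom <- rep(m %/% cfg$nChromosomes, cfg$nChromosomes)
  rem <- m %% cfg$nChromosomes
  if (rem > 0) perChrom[seq_len(rem)] <- perChrom[seq_len(rem)] + 1
  chromIndex <- rep(seq_len(cfg$nChromosomes), perChrom)
  posM <- unlist(lapply(perChrom, function(k) (seq_len(k) - 0.5) / k))
  map <- data.frame(snp_id = sprintf("snp%05d", seq_len(m)),
                    chrom = chromIndex,
                    pos = as.integer(round(posM * 1e8)))
  p <- stats::runif(m, cfg$founderMafRange[1], cfg$founderMafRange[2])
  H1 <- matrix(0L, n, m)
  H2 <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    s <- ped@sire[i]
    d <- ped@dam[i]
    H1[i, ] <- if (is.na(s)) stats::rbinom(m, 1, p) else
      .gamete(H1[s, ], H2[s, ], chromIndex, posM)
    H2[i, ] <- if (is.na(d)) stats::rbinom(m, 1, p) else
      .gamete(H1[d, ], H2[d, ], chromIndex, posM)
  }
  X <- H1 + H2
  storage.mode(X) <- "double"
  rownames(X) <- animalIds(ped)
  gen <- ped@birthYear - cfg$baseYear
  gen[is.na(gen)] <- 0L
  prob <- cfg$propGenotyped[pmin(gen, length(cfg$propGenotyped) - 1) + 1]
  flagged <- stats::runif(n) < prob
  keepCols <- seq_len(m)
  qtlCandidates <- sort(sample.int(m, cfg$nQtl))
  if (cfg$hideQtl) keepCols <- setdiff(keepCols, qtlCandidates)
  full <- GenotypeData(X, map = map, ids = animalIds(ped))
  obs <- GenotypeData(X[flagged, keepCols, drop = FALSE],
                      map = map[keepCols, , drop = FALSE],
                      ids = animalIds(ped)[flagged])
  attr(obs, "full") <- full
  attr(obs, "qtlCandidates") <- qtlCandidates
  obs
}

#' Simulate phenotypes with known truth
#'
#' Two modes. Genomic (`g` supplied): QTL effects are drawn multivariate
#' normal with the target genetic correlations, true breeding values are
#' `M_qtl %*% effects` over ALL animals (using the full matrix attached by
#' [dropGenotypes()]), and each trait is rescaled so the realized genetic
#' variance equals its `h2` target (phenotypic variance 1). Polygenic
#' (`g = NULL`): breeding values follow the pedigree, founders
#' `MVN(0, Sigma_g)` and offspring parent-average plus Mendelian sampling
#' with inbreeding-corrected variance. Phenotypes add contemporary-group and
#' parity effects and correlated residuals; records are attached to the
#' configured subset of animals.
#'
#' @param ped a [Pedigree-class].
#' @param g a [GenotypeData-class] from [dropGenotypes()] or `NULL`.
#' @param cfg the [simConfig()].
#' @return list with `phenotypes` (data.frame: `animal`, trait columns,
#'   `contemporary_group`, `parity_class`, `birth_year`) and `truth` (list:
#'   `tbv` matrix over all animals, `qtl`, `h2`, `sigmaA2`, `sigmaE2`,
#'   realized h2 and genetic correlations).
#' @export
simulatePhenotypes <- function(ped, g = NULL, cfg) {
  set.seed(cfg$seed + 2)
  n <- nAnimals(ped)
  nt <- cfg$nTraits
  sa <- sqrt(cfg$h2)
  if (!is.null(g)) {
    full <- attr(g, "full")
    if (is.null(full)) full <- g
    if (!identical(animalIds(full), animalIds(ped))) {
      stop("genotypes must cover all pedigree animals (use the matrix ",
           "from dropGenotypes())")
    }
    cand <- attr(g, "qtlCandidates")
    if (is.null(cand)) cand <- sort(sample.int(nSnp(full), cfg$nQtl))
    Mq <- centeredDosages(full)[, cand, drop = FALSE]
    B <- matrix(stats::rnorm(length(cand) * nt), ncol = nt) %*%
      chol(cfg$geneticCorrelations)
    tbv <- Mq %*% B
    for (t in seq_len(nt)) {
      v <- stats::var(tbv[, t])
      if (cfg$h2[t] == 0) {
        tbv[, t] <- 0
      } else {
        if (v == 0) stop("unattainable h2: QTLs carry no genetic variance")
        tbv[, t] <- tbv[, t] * sa[t] / sqrt(v)
      }
    }
    qtl <- data.frame(snp_id = snpMap(full)$snp_id[cand], column = cand)
  } else {
    F <- inbreeding(ped)
    ms <- .mendelianD(ped, F)     # Mendelian-sampling variance multiplier
    Sg <- diag(sa, nt) %*% cfg$geneticCorrelations %*% diag(sa, nt)
    lat <- attr(ped, "latentBV")
    if (is.null(lat) || cfg$h2[1] == 0) {
      tbv <- .polygenicTBV(ped, Sg, ms)
    } else {
      ## the pedigree was built under selection on a latent polygenic
      ## trait; keep it as trait 1 so the selection response carries into
      ## the phenotypes, and draw the other traits conditionally (exact
      ## for a Kronecker trait-by-pedigree covariance)
      tbv <- matrix(lat[animalIds(ped)], n, 1)
      if (nt > 1) {
        beta <- Sg[-1, 1, drop = FALSE] / Sg[1, 1]
        Srem <- Sg[-1, -1, drop = FALSE] -
          (Sg[-1, 1, drop = FALSE] %*% Sg[1, -1, drop = FALSE]) / Sg[1, 1]
        W <- .polygenicTBV(ped, Srem, ms)
        tbv <- cbind(tbv, tbv[, 1] %*% t(beta) + W)
      }
    }
    if (any(cfg$h2 == 0)) tbv[, cfg$h2 == 0] <- 0
    qtl <- NULL
  }
  rownames(tbv) <- animalIds(ped)
  colnames(tbv) <- cfg$traitNames

  gen <- ped@birthYear - cfg$baseYear
  recorded <- switch(cfg$phenotyped$rule,
    all = rep(TRUE, n),
    males = !is.na(ped@sex) & ped@sex == "M",
    nonfounders = !(is.na(ped@sire) & is.na(ped@dam)),
    stop("unknown phenotyped rule '", cfg$phenotyped$rule, "'"))
  recorded <- recorded & !is.na(gen) & gen >= cfg$phenotyped$fromGeneration
  if (!any(recorded)) stop("no animal satisfies the phenotyping rule")
  ridx <- which(recorded)
  nrec <- length(ridx)

  ## contemporary groups nested in birth year
  targetSize <- max(2, round(nrec / cfg$nContempGroups))
  cg <- character(nrec)
  for (yr in unique(ped@birthYear[ridx])) {
    inYr <- which(ped@birthYear[ridx] == yr)
    k <- max(1, round(length(inYr) / targetSize))
    cg[inYr] <- sprintf("y%d_g%02d", yr,
                        sample(rep(seq_len(k), length.out = length(inYr))))
  }
  cgLevels <- unique(cg)
  cgEff <- matrix(stats::rnorm(length(cgLevels) * nt, 0, cfg$sdCG),
                  ncol = nt, dimnames = list(cgLevels, NULL))
  parity <- sample.int(cfg$nParityClasses, nrec, replace = TRUE)
  parEff <- matrix(stats::rnorm(cfg$nParityClasses * nt, 0, cfg$sdParity),
                   ncol = nt)
  se <- sqrt(1 - cfg$h2)
  Se <- diag(se, nt) %*% cfg$residualCorrelations %*% diag(se, nt)
  res <- matrix(stats::rnorm(nrec * nt), nrec, nt) %*% chol(Se)
  Yp <- cgEff[cg, , drop = FALSE] + parEff[parity, , drop = FALSE] +
    tbv[ridx, , drop = FALSE] + res

  phen <- data.frame(animal = animalIds(ped)[ridx],
                     stringsAsFactors = FALSE)
  for (t in seq_len(nt)) phen[[cfg$traitNames[t]]] <- Yp[, t]
  phen$contemporary_group <- cg
  phen$parity_class <- factor(parity)
  phen$birth_year <- ped@birthYear[ridx]

  realized <- apply(tbv, 2, stats::var)
  list(phenotypes = phen,
       truth = list(tbv = tbv, qtl = qtl, h2 = cfg$h2,
                    sigmaA2 = cfg$h2, sigmaE2 = 1 - cfg$h2,
                    realizedH2 = realized / (realized + (1 - cfg$h2)),
                    realizedGeneticCor = if (nt > 1) stats::cor(tbv) else
                      NULL,
                    mode = if (is.null(g)) "polygenic" else "genomic"))
}

#' Bundled synthetic dataset shaped like a small alpine breed's
#' performance-test data
#'
#' One call producing a scaled emulation of a small dual-purpose cattle
#' population under performance testing: a multi-generation pedigree with
#' genotyping concentrated in the recent cohorts, three beef traits (ADG,
#' EUROP fleshiness score, dressing percentage) with heritability targets
#' 0.335, 0.304 and 0.392 and strong genetic correlation between the two
#' conformation traits (0.981), contemporary-group and parity fixed
#' effects, and phenotypes restricted to recent-generation males (the
#' performance-tested bulls). At `scale = 0.25` the pedigree holds about
#' 2100 animals with roughly 440 phenotyped and 440 genotyped.
#'
#' @param seed integer seed; the bundle is deterministic given it.
#' @param scale fraction in (0, 1] scaling population sizes.
#' @param nSnp marker panel size (default 2000).
#' @return list with `ped`, `genotypes` (observed cohort), `phenotypes`,
#'   `truth`, `cfg`.
#' @export
performanceTestDataset <- function(seed, scale = 0.25, nSnp = 2000) {
  stopifnot(scale > 0, scale <= 1)
  rg <- matrix(c(1, 0.364, 0.398,
                 0.364, 1, 0.981,
                 0.398, 0.981, 1), 3, 3)
  re <- matrix(c(1, 0.572, 0.613,
                 0.572, 1, 0.792,
                 0.613, 0.792, 1), 3, 3)
  cfg <- simConfig(
    seed = seed,
    nFounders = max(20, round(1200 * scale)),
    nGenerations = 6,
    nPerGeneration = max(20, round(1200 * scale)),
    offspringPerMating = 2,
    propGenotyped = c(0, 0, 0, 0, 0.2, 0.5, 0.75),
    nSnp = nSnp, nChromosomes = 10,
    founderMafRange = c(0.05, 0.5),
    nQtl = 100,
    h2 = c(0.335, 0.304, 0.392),
    traitNames = c("ADG", "EUROP", "DP"),
    geneticCorrelations = rg,
    residualCorrelations = re,
    nContempGroups = max(4, round(142 * scale)),
    nParityClasses = 4,
    sdCG = 0.5, sdParity = 0.2,
    phenotyped = list(rule = "males", fromGeneration = 4),
    baseYear = 2010)
  ped <- simulatePedigree(cfg)
  g <- dropGenotypes(ped, cfg)
  sim <- simulatePhenotypes(ped, g, cfg)
  list(ped = ped, genotypes = g, phenotypes = sim$phenotypes,
       truth = sim$truth, cfg = cfg)
}
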