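## Configuration-driven orchestration: simulate/load -> variance components
## -> fit models on whole and partial data -> LR validation -> report.

#' Validate a pipeline configuration
#'
#' Checks a configuration (a list, or the path of a YAML file) without
#' computing anything: data source, method names and their parameters,
#' variance-component mode, cut-off year. Used directly as the dry-run mode
#' of [runPipeline()].
#'
#' @param config list or YAML file path.
#' @return the normalized configuration list, invisibly on success; errors
#'   describe the offending entry.
#' @export
validateRunConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  if (is.null(config$seed)) config$seed <- 1
  if (is.null(config$outDir)) stop("config$outDir is required")
  if (is.null(config$data)) stop("config$data is required")
  src <- config$data
  if (is.null(src$simulate) &&
      (is.null(src$pedigree) || is.null(src$phenotypes))) {
    stop("config$data needs either $simulate (simConfig arguments) or ",
         "$pedigree + $phenotypes file paths")
  }
  if (is.null(config$traits)) stop("config$traits is required")
  if (is.null(config$fixed)) {
    config$fixed <- c("contemporary_group", "parity_class")
  }
  if (is.null(config$methods) || length(config$methods) == 0) {
    stop("at least one method required")
  }
  config$methods <- lapply(config$methods, function(m) {
    if (is.character(m)) m <- list(name = m)
    if (is.null(m$name) ||
        !m$name %in% c("PBLUP", "ssGBLUP", "WssGBLUP")) {
      stop("unknown method name '", m$name, "'")
    }
    if (m$name == "WssGBLUP") {
      if (is.null(m$CT)) stop("WssGBLUP method needs CT")
      if (is.null(m$nIter)) m$nIter <- 2
    }
    m
  })
  vc <- config$varcomp
  if (is.null(vc)) stop("config$varcomp is required")
  if (is.null(vc$mode) || !vc$mode %in% c("fixed", "gibbs")) {
    stop("config$varcomp$mode must be 'fixed' or 'gibbs'")
  }
  if (vc$mode == "fixed" &&
      (is.null(vc$sigmaA2) || is.null(vc$sigmaE2))) {
    stop("fixed varcomp mode needs sigmaA2 and sigmaE2 (per trait)")
  }
  if (is.null(config$cutoffYear)) {
    stop("config$cutoffYear is required for LR validation")
  }
  invisible(config)
}

.stageBanner <- function(name) {
  message(sprintf("[%s] stage: %s", format(Sys.time(), "%H:%M:%S"), name))
}

#' Run the full evaluation pipeline
#'
#' Executes simulate (or load) -> variance components -> model fits on the
#' whole and birth-year-truncated datasets -> LR cross-validation ->
#' report, writing every intermediate artifact (with an MD5 manifest) under
#' `config$outDir`. The report has one row per method and trait with the
#' LR estimators and, for genomic methods, the adjusted accuracy gain over
#' PBLUP.
#'
#' @param config list or YAML file path (see [validateRunConfig()]).
#' @param dryRun if TRUE, only validate and return the normalized config.
#' @return list with `report` (data.frame), `solutions` (nested list of
#'   [SolutionSet-class]), `varcomp`, and `outDir`.
#' @export
runPipeline <- function(config, dryRun = FALSE) {
  config <- validateRunConfig(config)
  if (dryRun) return(config)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()

  .stageBanner("data")
  if (!is.null(config$data$simulate)) {
    cfgSim <- do.call(simConfig, c(config$data$simulate,
                                   list(seed = config$seed)))
    ped <- simulatePedigree(cfgSim)
    g <- if (any(cfgSim$propGenotyped > 0)) dropGenotypes(ped, cfgSim)
         else NULL
    sim <- simulatePhenotypes(ped, g, cfgSim)
    phen <- sim$phenotypes
    writePedigree(ped, file.path(config$outDir, "pedigree.csv"))
    writePhenotypes(phen, file.path(config$outDir, "phenotypes.csv"))
    if (!is.null(g)) {
      writeGenotypes(g, file.path(config$outDir, "genotypes.raw"),
                     mapPath = file.path(config$outDir, "snp_map.tsv"))
    }
  } else {
    ped <- readPedigree(config$data$pedigree)
    phen <- readPhenotypes(config$data$phenotypes)
    g <- if (!is.null(config$data$genotypes)) {
      readGenotypes(config$data$genotypes,
                    format = if (is.null(config$data$genotypeFormat)) "raw"
                             else config$data$genotypeFormat,
                    mapPath = config$data$map)
    } else NULL
  }
  genotypedIds <- if (is.null(g)) animalIds(ped) else animalIds(g)
  data <- list(ped = ped, phenotypes = phen, genotypes = g)

  .stageBanner("varcomp")
  vc <- config$varcomp
  varcomp <- list()
  for (tr in config$traits) {
    if (vc$mode == "fixed") {
      i <- match(tr, config$traits)
      varcomp[[tr]] <- list(
        sigmaA2 = .perTrait(vc$sigmaA2, i),
        sigmaE2 = .perTrait(vc$sigmaE2, i))
    } else {
      des <- buildDesign(phen, ped, tr, fixed = config$fixed)
      post <- gibbsUnivariate(
        des, makeAinverse(ped),
        chain = if (is.null(vc$chain)) 20000 else vc$chain,
        burnIn = if (is.null(vc$burnIn)) 2000 else vc$burnIn,
        thin = if (is.null(vc$thin)) 10 else vc$thin,
        seed = config$seed)
      sm <- posteriorSummary(post)
      varcomp[[tr]] <- list(
        sigmaA2 = sm$mean[sm$parameter == "sigma2_a"],
        sigmaE2 = sm$mean[sm$parameter == "sigma2_e"],
        posterior = sm)
    }
  }

  .stageBanner("fit + LR validation")
  split <- makePartial(phen, ped, genotypedIds, config$cutoffYear)
  rows <- list()
  sols <- list()
  for (tr in config$traits) {
    sA2 <- varcomp[[tr]]$sigmaA2
    sE2 <- varcomp[[tr]]$sigmaE2
    F <- inbreeding(ped)
    Fbar <- mean(F[split$focal])
    pblupPartial <- NULL
    for (m in config$methods) {
      tag <- if (m$name == "WssGBLUP") {
        sprintf("WssGBLUP_CT%.3f_it%d", m$CT, m$nIter)
      } else m$name
      fitOne <- function(ph, dsTag) {
        d <- list(ped = ped, phenotypes = ph, genotypes = g)
        if (m$name == "WssGBLUP") {
          it <- wssgblup(d, tr, CT = m$CT, limit = m$limit,
                         nIter = m$nIter, sigmaA2 = sA2, sigmaE2 = sE2,
                         fixed = config$fixed)
          last <- it[[length(it)]]
          if (dsTag == "PARTIAL") {
            writeWeightTrajectory(it, g,
              file.path(config$outDir, sprintf("%s_%s", tag, tr)))
          }
          s <- last$solutions
          s@modelTag <- tag
          s@datasetTag <- dsTag
          s
        } else {
          runModel(d, tr, method = m$name, sigmaA2 = sA2, sigmaE2 = sE2,
                   fixed = config$fixed, datasetTag = dsTag)
        }
      }
      solW <- fitOne(phen, "WHOLE")
      solP <- fitOne(split$partial, "PARTIAL")
      sols[[tr]][[tag]] <- list(whole = solW, partial = solP)
      writeSolutions(solW, file.path(config$outDir,
                                     sprintf("%s_%s_whole", tag, tr)))
      writeSolutions(solP, file.path(config$outDir,
                                     sprintf("%s_%s_partial", tag, tr)))
      if (m$name == "PBLUP") pblupPartial <- ebv(solP)[split$focal]
      st <- lrStatistics(ebv(solP)[split$focal], ebv(solW)[split$focal],
                         sigmaA = sqrt(sA2), Fmean = Fbar, sigmaU2 = sA2)
      gain <- if (m$name != "PBLUP" && !is.null(pblupPartial)) {
        genomicGain(pblupPartial, ebv(solP)[split$focal],
                    varA = sA2, varG = sA2)
      } else list(inc = NA_real_, inc_adj = NA_real_)
      rows[[length(rows) + 1]] <- data.frame(
        trait = tr, method = tag, n_focal = st$n_focal,
        acc = st$acc, bias = st$bias, bias_std = st$bias_std,
        dispersion = st$dispersion, rel = st$rel,
        inc_adj = gain$inc_adj)
    }
    trend <- geneticTrend(sols[[tr]][[1]]$whole, ped, sqrt(sA2))
    utils::write.table(trend,
                       file.path(config$outDir,
                                 sprintf("trend_%s.tsv", tr)),
                       quote = FALSE, row.names = FALSE, sep = "\t")
  }
  report <- do.call(rbind, rows)
  utils::write.table(report, file.path(config$outDir, "lr_report.tsv"),
                     quote = FALSE, row.names = FALSE, sep = "\t")

  manifest <- list.files(config$outDir, full.names = TRUE)
  manifest <- manifest[!grepl("MANIFEST", manifest)]
  md5 <- tools::md5sum(manifest)
  utils::write.table(data.frame(file = basename(names(md5)), md5 = md5),
                     file.path(config$outDir, "MANIFEST.tsv"),
                     quote = FALSE, row.names = FALSE, sep = "\t")
  message(sprintf("pipeline finished in %.1f s",
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  list(report = report, solutions = sols, varcomp = varcomp,
       outDir = config$outDir)
}

.perTrait <- function(x, i) {
  if (length(x) == 1) as.numeric(x) else as.numeric(x[[i]])
}

#' Write per-iteration weight, effect, and window-variance tables
#'
#' @param iterations result of [wssgblup()].
#' @param g the [GenotypeData-class] used in the fit.
#' @param stem output path stem.
#' @return invisibly, the written paths.
#' @export
writeWeightTrajectory <- function(iterations, g, stem) {
  paths <- character(0)
  for (t in seq_along(iterations)) {
    it <- iterations[[t]]
    pw <- sprintf("%s_it%d_weights.tsv", stem, t)
    utils::write.table(
      data.frame(snp_id = snpMap(g)$snp_id, d = it$weights@d),
      pw, quote = FALSE, row.names = FALSE, sep = "\t")
    pe <- sprintf("%s_it%d_effects.tsv", stem, t)
    utils::write.table(
      data.frame(snp_id = snpMap(g)$snp_id, u = it$effects@u),
      pe, quote = FALSE, row.names = FALSE, sep = "\t")
    pm <- sprintf("%s_it%d_windows.tsv", stem, t)
    utils::write.table(windowVariance(it$effects, g), pm, quote = FALSE,
                       row.names = FALSE, sep = "\t")
    paths <- c(paths, pw, pe, pm)
  }
  invisible(paths)
}
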