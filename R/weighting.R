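## nonlinearA SNP weighting: backsolved effects, shrinkage weights,
## trace normalization, and the iterative weighted single-step loop.

#' Backsolve SNP effects from genomic EBVs
#'
#' Recovers per-SNP allele-substitution effects from the EBVs of the
#' genotyped animals by
#' \eqn{\hat u = \delta\, D M' (M D M')^{-1} \hat a}. When `M D M'` is
#' numerically singular (more animals than SNPs, or redundant markers) a
#' ridge of `1e-8 * mean(diag)` is added. The absolute scale of `u` is
#' arbitrary up to `delta`; the weighting rule uses only
#' \eqn{|\hat u_i| / sd(\hat u)}.
#'
#' @param ebvG numeric vector of genotyped-animal EBVs, named by or aligned
#'   with `animalIds(g)`.
#' @param g a [GenotypeData-class] (post-QC).
#' @param weights current [SnpWeights-class], numeric vector, or `NULL` for
#'   unit weights.
#' @param delta base-scale constant (default 1).
#' @return A [SnpEffects-class].
#' @export
backsolveSnpEffects <- function(ebvG, g, weights = NULL, delta = 1) {
  M <- centeredDosages(g)
  if (length(ebvG) != nrow(M)) {
    stop("EBV vector length != number of genotyped animals")
  }
  if (!is.null(names(ebvG))) {
    if (!setequal(names(ebvG), animalIds(g))) {
      stop("EBV names do not match genotyped animals")
    }
    ebvG <- ebvG[animalIds(g)]
  }
  d <- if (is.null(weights)) rep(1, ncol(M)) else
    if (is(weights, "SnpWeights")) weights@d else as.numeric(weights)
  if (length(d) != ncol(M)) stop("weights length != number of SNPs")
  MD <- sweep(M, 2, d, "*")
  MDM <- tcrossprod(MD, M)
  MDM <- (MDM + t(MDM)) / 2
  ## MDM' is rank-deficient whenever n_snp < n_animals; regularize with a
  ## small ridge in that case (and whenever it is ill-conditioned)
  if (ncol(M) < nrow(M) || rcond(MDM) < 1e-10) {
    MDM <- MDM + diag(1e-8 * mean(diag(MDM)), nrow(MDM))
  }
  sol <- solve(MDM, ebvG)
  u <- delta * d * as.numeric(crossprod(M, sol))
  names(u) <- snpMap(g)$snp_id
  new("SnpEffects", u = u, sdU = stats::sd(u), delta = delta)
}

#' nonlinearA shrinkage weights
#'
#' The nonlinearA rule departs from the equal-variance assumption of the
#' plain genomic matrix by giving SNP i the weight
#' \eqn{d_i = CT^{\,|\hat u_i|/sd(\hat u) - 2}}: effects two standard
#' deviations from zero keep weight 1, larger ones are promoted, smaller
#' ones shrunk. Weights are capped at `limit` and floored at `1/limit`. The
#' default cap is `CT^(5-2) = CT^3` — 1.350, 1.424 and 1.953 for the usual
#' CT values 1.105, 1.125 and 1.250.
#'
#' @param eff a [SnpEffects-class] (or numeric vector of effects).
#' @param CT shrinkage base, > 1.
#' @param limit cap on a weight, or `NULL` for the default `CT^3`.
#' @param iteration iteration index stored in the result.
#' @return A [SnpWeights-class] (not yet trace-normalized).
#' @export
nonlinearAWeights <- function(eff, CT, limit = NULL, iteration = 2L) {
  if (CT <= 1) stop("CT must be greater than 1")
  if (is.null(limit)) limit <- CT^3
  if (limit <= 1) stop("limit must be greater than 1")
  u <- if (is(eff, "SnpEffects")) eff@u else as.numeric(eff)
  s <- stats::sd(u)
  if (!is.finite(s) || s == 0) {
    warning("sd of SNP effects is zero; all weights set to 1")
    d <- rep(1, length(u))
  } else {
    d <- CT^(abs(u) / s - 2)
    d <- pmin(pmax(d, 1 / limit), limit)
  }
  new("SnpWeights", d = unname(d), CT = CT, limit = limit,
      iteration = as.integer(iteration), traceRef = length(u))
}

#' Trace-normalize SNP weights
#'
#' Rescales weights so the trace of D equals its iteration-1 reference (the
#' SNP count), keeping total genetic variance constant across iterations.
#' Plain rescaling can push capped weights past the bound, so the scaling is
#' applied water-filling style: weights pinned at `limit` (or `1/limit`)
#' stay at the bound and the free weights absorb the remaining trace. Both
#' the cap and the exact trace therefore hold on exit.
#'
#' @param w a [SnpWeights-class].
#' @return A [SnpWeights-class] with `sum(d) == traceRef`.
#' @export
normalizeWeights <- function(w) {
  stopifnot(is(w, "SnpWeights"))
  d0 <- w@d
  target <- w@traceRef
  lim <- w@limit
  lo <- if (is.finite(lim)) 1 / lim else 0
  hi <- if (is.finite(lim)) lim else Inf
  n <- length(d0)
  if (target < n * lo - 1e-12 || target > n * hi + 1e-12) {
    warning("reference trace unreachable within the weight bounds")
    d <- pmin(pmax(d0 * target / sum(d0), lo), hi)
  } else {
    ## find the common scale s with sum(clamp(s * d0, lo, hi)) == target;
    ## the left side is monotone in s, so bisect
    f <- function(s) sum(pmin(pmax(s * d0, lo), hi)) - target
    sLo <- lo / max(d0)
    sHi <- if (is.finite(hi)) hi / min(d0) else
      target / sum(d0) * 1e6
    for (i in 1:200) {
      sMid <- (sLo + sHi) / 2
      if (f(sMid) < 0) sLo <- sMid else sHi <- sMid
    }
    d <- pmin(pmax(sMid * d0, lo), hi)
    ## absorb the bisection residual on the strictly interior weights
    free <- d > lo + 1e-12 & d < hi - 1e-12
    if (any(free)) {
      d[free] <- d[free] + (target - sum(d)) / sum(free)
      d <- pmin(pmax(d, lo), hi)
    }
  }
  if (abs(sum(d) - target) > 1e-8 * max(target, 1)) {
    warning("trace normalization could not reach the reference trace ",
            "exactly under the weight bounds")
  }
  new("SnpWeights", d = d, CT = w@CT, limit = w@limit,
      iteration = w@iteration, traceRef = w@traceRef)
}

#' Iteratively weighted single-step GBLUP
#'
#' Runs the weighted single-step loop: start at `D = I` (iteration 1 is
#' exactly ssGBLUP), solve the single-step MME, backsolve SNP effects from
#' the genotyped animals' GEBVs, compute nonlinearA weights with cap,
#' trace-normalize, rebuild the genomic matrix (tune, blend, H-inverse) and
#' re-solve. By default the tuning and blending are redone from scratch
#' every iteration.
#'
#' @param data list with `ped`, `phenotypes`, `genotypes` (see [runModel()]).
#' @param trait trait column name.
#' @param CT shrinkage base (> 1).
#' @param limit weight cap, `NULL` for the default `CT^3`.
#' @param nIter number of iterations (>= 1).
#' @param sigmaA2,sigmaE2,lambda variance components (see [solveMME()]).
#' @param fixed fixed-effect columns.
#' @param alpha,beta,tune kernel options (see [buildKernel()]).
#' @param earlyStop stop when successive weight vectors correlate above this
#'   value (`NULL` disables; default `NULL`).
#' @return list of per-iteration lists, each with `solutions`
#'   ([SolutionSet-class]), `weights` ([SnpWeights-class], the weights that
#'   BUILT that iteration's G), and `effects` ([SnpEffects-class], backsolved
#'   from that iteration's GEBVs).
#' @export
wssgblup <- function(data, trait, CT, limit = NULL, nIter = 2,
                     sigmaA2 = NULL, sigmaE2 = NULL, lambda = NULL,
                     fixed = c("contemporary_group", "parity_class"),
                     alpha = 0.95, beta = 0.05, tune = TRUE,
                     earlyStop = NULL) {
  if (is.null(data$genotypes)) stop("wssgblup requires genotypes")
  stopifnot(nIter >= 1)
  g <- data$genotypes
  nsnp <- nSnp(g)
  w <- new("SnpWeights", d = rep(1, nsnp), CT = NA_real_,
           limit = if (is.null(limit)) {
             if (CT > 1) CT^3 else Inf
           } else limit,
           iteration = 1L, traceRef = nsnp)
  out <- vector("list", nIter)
  for (t in seq_len(nIter)) {
    sol <- runModel(data, trait,
                    method = if (t == 1) "ssGBLUP" else "WssGBLUP",
                    sigmaA2 = sigmaA2, sigmaE2 = sigmaE2, lambda = lambda,
                    weights = if (t == 1) NULL else w, fixed = fixed,
                    alpha = alpha, beta = beta, tune = tune)
    if (any(!is.finite(ebv(sol)))) {
      stop("non-finite solutions at iteration ", t)
    }
    aG <- ebv(sol)[animalIds(g)]
    eff <- backsolveSnpEffects(aG, g, weights = if (t == 1) NULL else w)
    wNew <- nonlinearAWeights(eff, CT = CT, limit = limit,
                              iteration = t + 1L)
    wNew@traceRef <- nsnp
    wNew <- normalizeWeights(wNew)
    out[[t]] <- list(solutions = sol, weights = w, effects = eff)
    if (!is.null(earlyStop) && t > 1 &&
        stats::cor(wNew@d, w@d) > earlyStop) {
      w <- wNew
      out <- out[seq_len(t)]
      break
    }
    w <- wNew
  }
  out
}

#' Variance explained by consecutive SNP windows
#'
#' Partitions the map-ordered SNPs into consecutive non-overlapping blocks
#' of `windowSize` (the last block may be short) and reports the percentage
#' of genomic variance each window explains:
#' `100 * Var(M_w u_w) / Var(M u)` over the genotyped animals, with the
#' chromosome and midpoint position of each window (a Manhattan-plot table).
#'
#' @param eff a [SnpEffects-class] (or numeric vector aligned with the map).
#' @param g a [GenotypeData-class].
#' @param windowSize number of SNPs per window (default 20).
#' @return data.frame with `chrom`, `start`, `end`, `mid`, `n_snp`,
#'   `pct_var`.
#' @export
windowVariance <- function(eff, g, windowSize = 20) {
  u <- if (is(eff, "SnpEffects")) eff@u else as.numeric(eff)
  if (length(u) == 0) stop("empty effects vector")
  if (length(u) != nSnp(g)) stop("effects length != number of SNPs")
  stopifnot(windowSize >= 1)
  M <- centeredDosages(g)
  total <- stats::var(as.numeric(M %*% u))
  if (total == 0) stop("zero genomic variance: all effects null")
  map <- snpMap(g)
  win <- (seq_along(u) - 1) %/% windowSize
  ## windows never span chromosomes
  win <- as.integer(factor(paste(map$chrom, win, sep = "_"),
                           levels = unique(paste(map$chrom, win,
                                                 sep = "_"))))
  res <- lapply(split(seq_along(u), win), function(ix) {
    v <- stats::var(as.numeric(M[, ix, drop = FALSE] %*% u[ix]))
    data.frame(chrom = map$chrom[ix[1]],
               start = map$pos[ix[1]],
               end = map$pos[ix[length(ix)]],
               mid = map$pos[ix[ceiling(length(ix) / 2)]],
               n_snp = length(ix),
               pct_var = 100 * v / total)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
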