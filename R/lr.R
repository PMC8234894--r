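## LR-method cross-validation: whole/partial split, the bias / dispersion /
## accuracy / reliability estimators, genomic accuracy gain, genetic trend.

#' Whole/partial split and focal group for LR validation
#'
#' Truncates the phenotype table by the birth year of the phenotyped animal:
#' the partial dataset keeps records of animals born in or before
#' `cutoffYear`; the focal individuals are the genotyped animals born after
#' it (the young selection candidates whose records exist only in the whole
#' data).
#'
#' @param phenotypes data.frame with `animal` and trait columns.
#' @param ped a [Pedigree-class] (source of birth years).
#' @param genotypedIds ids of genotyped animals; for a pedigree-only
#'   analysis pass all animal ids.
#' @param cutoffYear integer cut-off birth year.
#' @return list with `partial` (truncated phenotype data.frame), `focal`
#'   (character ids) and `cutoffYear`.
#' @export
makePartial <- function(phenotypes, ped, genotypedIds, cutoffYear) {
  by <- stats::setNames(ped@birthYear, animalIds(ped))
  phYear <- by[as.character(phenotypes$animal)]
  if (all(is.na(phYear))) stop("no birth years available")
  partial <- phenotypes[!is.na(phYear) & phYear <= cutoffYear, ,
                        drop = FALSE]
  if (nrow(partial) == 0) {
    stop("empty partial dataset: cut-off year precedes all phenotyped ",
         "animals")
  }
  gidYear <- by[as.character(genotypedIds)]
  focal <- as.character(genotypedIds)[!is.na(gidYear) &
                                      gidYear > cutoffYear]
  if (length(focal) == 0) {
    stop("empty focal group: no genotyped animal born after ", cutoffYear)
  }
  list(partial = partial, focal = focal, cutoffYear = cutoffYear)
}

#' LR cross-validation estimators
#'
#' Given the focal animals' EBVs from the partial (`uP`) and whole (`uW`)
#' data:
#' \itemize{
#'   \item bias \eqn{= \bar u_p - \bar u_w} (expectation 0), also
#'     standardized by the genetic standard deviation;
#'   \item dispersion \eqn{= cov(u_w, u_p)/var(u_p)}, the slope of whole on
#'     partial (expectation 1; below 1 flags over-dispersion);
#'   \item accuracy ratio \eqn{acc = cov(u_w,u_p)/\sqrt{var(u_p) var(u_w)}};
#'   \item reliability \eqn{rel = cov(u_w,u_p)/((1-\bar F)\sigma^2_u)} with
#'     \eqn{\bar F} the mean inbreeding of the focal group and
#'     \eqn{\sigma^2_u} the whole-data genetic variance.
#' }
#' Sample (n-1) variances and covariances are used throughout.
#'
#' @param uP,uW aligned numeric vectors of focal EBVs (length >= 2).
#' @param sigmaA genetic standard deviation used to standardize the bias.
#' @param Fmean mean inbreeding coefficient (default 0).
#' @param sigmaU2 genetic variance for the reliability (default
#'   `sigmaA^2`).
#' @return list of class fields: `bias`, `bias_std`, `dispersion`, `acc`,
#'   `rel`, `n_focal`.
#' @export
lrStatistics <- function(uP, uW, sigmaA, Fmean = 0, sigmaU2 = sigmaA^2) {
  if (length(uP) != length(uW)) stop("uP and uW must be aligned")
  if (length(uP) < 2) stop("need at least 2 focal animals")
  vP <- stats::var(uP)
  if (vP == 0) stop("zero variance in partial EBVs: dispersion undefined")
  cv <- stats::cov(uW, uP)
  list(bias = mean(uP) - mean(uW),
       bias_std = (mean(uP) - mean(uW)) / sigmaA,
       dispersion = cv / vP,
       acc = cv / sqrt(vP * stats::var(uW)),
       rel = cv / ((1 - Fmean) * sigmaU2),
       n_focal = length(uP))
}

#' Accuracy gain from adding genomic information
#'
#' From partial-data EBVs of the focal group under the pedigree model
#' (`uA`) and a genomic model (`uG`): the correlation
#' \eqn{\rho_{A,G} = cov(u_A,u_G)/\sqrt{var(u_A) var(u_G)}} estimates the
#' inverse of the accuracy gain, so `inc` \eqn{= \rho^{-1} - 1}; `inc_adj`
#' rescales it by the ratio of the two models' genetic variances,
#' \eqn{(\sigma^2_A/\sigma^2_G)\, inc}.
#'
#' @param uA,uG aligned focal EBV vectors from the pedigree and genomic
#'   models (partial data).
#' @param varA,varG genetic variances estimated without and with genomic
#'   information (default 1: unadjusted).
#' @return list with `rho`, `inc`, `inc_adj`.
#' @export
genomicGain <- function(uA, uG, varA = 1, varG = 1) {
  if (length(uA) != length(uG)) stop("uA and uG must be aligned")
  rho <- stats::cor(uA, uG)
  if (!is.finite(rho) || rho <= 0) {
    stop("non-positive correlation between pedigree and genomic EBVs: ",
         "accuracy-gain estimator undefined")
  }
  inc <- 1 / rho - 1
  list(rho = rho, inc = inc, inc_adj = (varA / varG) * inc)
}

#' Standardized genetic trend by birth year
#'
#' Mean EBV per birth year divided by the genetic standard deviation, with
#' the ordinary-least-squares slope per year.
#'
#' @param solutions a [SolutionSet-class].
#' @param ped a [Pedigree-class] with birth years.
#' @param sigmaA genetic standard deviation.
#' @return data.frame with `year`, `n`, `mean_std_ebv`; the regression
#'   slope (genetic SD per year) is attached as `attr(, "slope")`.
#' @export
geneticTrend <- function(solutions, ped, sigmaA) {
  a <- ebv(solutions)[animalIds(ped)]
  yr <- ped@birthYear
  ok <- !is.na(yr)
  df <- stats::aggregate(list(std_ebv = a[ok] / sigmaA),
                         by = list(year = yr[ok]), FUN = mean)
  cnt <- as.data.frame(table(yr[ok]))
  out <- data.frame(year = df$year,
                    n = cnt$Freq[match(df$year, as.integer(
                      as.character(cnt$Var1)))],
                    mean_std_ebv = df$std_ebv)
  out <- out[order(out$year), ]
  rownames(out) <- NULL
  slope <- if (nrow(out) > 1) {
    unname(stats::coef(stats::lm(mean_std_ebv ~ year, data = out))[2])
  } else NA_real_
  attr(out, "slope") <- slope
  out
}
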