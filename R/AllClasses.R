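#' @import methods
#' @importFrom Matrix Matrix sparseMatrix crossprod t solve Cholesky
#'   forceSymmetric Diagonal drop0 bdiag update
#' @importFrom stats var cov cor rnorm runif rbinom rchisq rpois rWishart sd
#'   model.matrix aggregate coef lm quantile complete.cases setNames
#' @importFrom utils read.table write.table read.csv
#' @importFrom tools md5sum
NULL

setClassUnion("integerOrNULL", c("integer", "NULL"))

#' Pedigree of a managed population
#'
#' An S4 container for a validated, topologically sorted pedigree. Animals are
#' stored in an order where every parent precedes its offspring, so that the
#' recursive relationship algebra (tabular A, Meuwissen-Luo inbreeding,
#' Henderson's sparse A-inverse) can run in a single forward pass. Parents are
#' held as integer indexes into the same object, with `NA` marking an unknown
#' parent; founders have both parents unknown and are treated as unrelated and
#' non-inbred (no genetic groups).
#'
#' @slot id character vector of unique animal identifiers, in sorted order.
#' @slot sire,dam integer index of each animal's parent within this object,
#'   `NA` if unknown. Always smaller than the animal's own index.
#' @slot birthYear integer birth year (NA allowed).
#' @slot sex character, `"M"`, `"F"` or `NA`.
#'
#' @seealso [Pedigree()], [inbreeding()], [makeA()], [makeAinverse()]
#' @export
setClass("Pedigree",
  representation(
    id = "character",
    sire = "integer",
    dam = "integer",
    birthYear = "integer",
    sex = "character"
  )
)

setValidity("Pedigree", function(object) {
  n <- length(object@id)
  msgs <- character(0)
  if (anyDuplicated(object@id)) {
    msgs <- c(msgs, sprintf("duplicate animal id '%s'",
                            object@id[anyDuplicated(object@id)]))
  }
  for (sl in c("sire", "dam", "birthYear", "sex")) {
    if (length(slot(object, sl)) != n) {
      msgs <- c(msgs, sprintf("slot '%s' length != number of animals", sl))
    }
  }
  idx <- seq_len(n)
  bad <- which(!is.na(object@sire) & object@sire >= idx)
  bad <- c(bad, which(!is.na(object@dam) & object@dam >= idx))
  if (length(bad)) {
    msgs <- c(msgs, sprintf(
      "pedigree not sorted: parent does not precede offspring for '%s'",
      paste(object@id[unique(bad)], collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' Relationship matrix with identity labels
#'
#' Wraps one realized relationship (or inverse-relationship) matrix together
#' with the animal identifiers that give its rows and columns meaning, and a
#' `kind` tag recording its role in the single-step algebra: `"A"` (numerator
#' relationship), `"A_INV"`, `"A22"`, `"A22_INV"`, `"G_RAW"` (VanRaden),
#' `"G_TUNED"`, `"G_BLEND"`, or `"H_INV"`. Inverses built by Henderson's rules
#' (`A_INV`, `H_INV`) are stored sparse (`Matrix` classes); the genomic kinds
#' are dense.
#'
#' @slot kind character tag, one of the kinds above.
#' @slot matrix the symmetric matrix (base `matrix` or a `Matrix` sparse
#'   class).
#' @slot ids character vector: animal id of each row/column.
#'
#' @seealso [makeA()], [vanRadenG()], [hInverse()]
#' @export
setClass("RelationshipMatrix",
  representation(kind = "character", matrix = "ANY", ids = "character")
)

.rel_kinds <- c("A", "A_INV", "A22", "A22_INV", "G_RAW", "G_TUNED",
                "G_BLEND", "H_INV")

setValidity("RelationshipMatrix", function(object) {
  msgs <- character(0)
  if (!object@kind %in% .rel_kinds) {
    msgs <- c(msgs, sprintf("unknown kind '%s'", object@kind))
  }
  m <- object@matrix
  if (nrow(m) != ncol(m)) msgs <- c(msgs, "matrix not square")
  if (length(object@ids) != nrow(m)) {
    msgs <- c(msgs, "ids length != matrix order")
  }
  asym <- max(abs(m - Matrix::t(m)))
  if (asym > 1e-10) {
    msgs <- c(msgs, sprintf("matrix not symmetric (max asymmetry %.2e)", asym))
  }
  if (object@kind %in% c("A", "A22") && any(diag(as.matrix(m)) < 1 - 1e-10)) {
    msgs <- c(msgs, "A-kind diagonal below 1")
  }
  if (length(msgs)) msgs else TRUE
})

#' Genotype dosages with SNP map
#'
#' Holds an animals-by-SNP matrix of additive dosages (0/1/2 counted-allele
#' copies; real-valued after mean imputation), the SNP map (chromosome and
#' base-pair position, kept sorted by chromosome then position), and the
#' per-SNP allele frequencies of the counted allele observed in the stored
#' animals. Missing dosages (`NA`) are only expected before [qcFilter()].
#'
#' @slot dosage numeric matrix, rows = animals, columns = SNPs.
#' @slot ids character animal identifiers (rownames of `dosage`).
#' @slot map data.frame with columns `snp_id`, `chrom`, `pos`.
#' @slot freqs numeric per-SNP frequency of the counted allele.
#'
#' @seealso [GenotypeData()], [qcFilter()], [vanRadenG()]
#' @export
setClass("GenotypeData",
  representation(dosage = "matrix", ids = "character",
                 map = "data.frame", freqs = "numeric")
)

setValidity("GenotypeData", function(object) {
  msgs <- character(0)
  if (nrow(object@dosage) != length(object@ids)) {
    msgs <- c(msgs, "ids length != number of dosage rows")
  }
  if (ncol(object@dosage) != nrow(object@map)) {
    msgs <- c(msgs, "map rows != number of SNP columns")
  }
  if (length(object@freqs) != ncol(object@dosage)) {
    msgs <- c(msgs, "freqs length != number of SNPs")
  }
  if (!all(c("snp_id", "chrom", "pos") %in% names(object@map))) {
    msgs <- c(msgs, "map must have columns snp_id, chrom, pos")
  }
  if (length(object@dosage) && !all(is.na(object@dosage))) {
    rng <- range(object@dosage, na.rm = TRUE)
    if (rng[1] < -1e-8 || rng[2] > 2 + 1e-8) {
      msgs <- c(msgs, "dosages outside [0, 2]")
    }
  }
  o <- order(object@map$chrom, object@map$pos)
  if (!identical(o, seq_len(nrow(object@map)))) {
    msgs <- c(msgs, "SNP map not sorted by (chrom, pos)")
  }
  if (length(msgs)) msgs else TRUE
})

#' Solutions of one mixed-model run
#'
#' Fixed-effect estimates and EBVs from one solve of Henderson's mixed-model
#' equations on one dataset. EBVs cover every pedigree animal, phenotyped or
#' not; the fixed part uses drop-first-level dummy coding with an explicit
#' intercept.
#'
#' @slot fixed data.frame with columns `effect`, `level`, `estimate`.
#' @slot ebv named numeric vector, one entry per pedigree animal (trait
#'   units).
#' @slot modelTag character, e.g. `"PBLUP"`, `"ssGBLUP"`, `"WssGBLUP_it2"`.
#' @slot datasetTag character, `"WHOLE"` or `"PARTIAL"`.
#' @slot converged logical: normal-equation residual below tolerance.
#'
#' @seealso [solveMME()], [runModel()]
#' @export
setClass("SolutionSet",
  representation(fixed = "data.frame", ebv = "numeric", modelTag = "character",
                 datasetTag = "character", converged = "logical")
)

setValidity("SolutionSet", function(object) {
  if (is.null(names(object@ebv))) return("ebv must be named by animal id")
  TRUE
})

#' Per-SNP weights for the weighted genomic relationship matrix
#'
#' Diagonal weights `d` of the weighted VanRaden matrix
#' \eqn{G_w = M D M' / (2\sum p_i(1-p_i))}, produced by the nonlinearA rule
#' with shrinkage base `CT` and cap `limit`, and trace-normalized so the total
#' SNP variance is conserved across iterations.
#'
#' @slot d numeric positive weights, one per SNP.
#' @slot CT shrinkage base (> 1), or `NA` for unit weights.
#' @slot limit upper cap on a weight; the floor is `1/limit`.
#' @slot iteration integer iteration index (1 = unweighted).
#' @slot traceRef reference trace (number of SNPs at iteration 1).
#' @export
setClass("SnpWeights",
  representation(d = "numeric", CT = "numeric", limit = "numeric",
                 iteration = "integer", traceRef = "numeric")
)

setValidity("SnpWeights", function(object) {
  if (any(object@d <= 0)) return("weights must be positive")
  if (length(object@limit) == 1 && is.finite(object@limit) &&
      any(object@d > object@limit + 1e-8)) {
    return("weights exceed the cap")
  }
  TRUE
})

#' Backsolved allele-substitution effects
#'
#' Per-SNP effects recovered from the GEBVs of the genotyped animals,
#' \eqn{\hat u = \delta D M'(M D M')^{-1}\hat a}. The absolute scale is
#' arbitrary up to the base-change constant `delta`; the nonlinearA weights
#' depend only on \eqn{|\hat u_i|/sd(\hat u)} and are invariant to it.
#'
#' @slot u numeric effects, one per SNP (trait units per allele copy).
#' @slot sdU standard deviation of `u`.
#' @slot delta base-scale constant used (default 1).
#' @export
setClass("SnpEffects",
  representation(u = "numeric", sdU = "numeric", delta = "numeric")
)

#' Retained draws of a Gibbs chain over variance components
#'
#' @slot draws numeric matrix, one row per retained draw; columns are named
#'   variance/covariance parameters (`sigma2_a`, `sigma2_e` for the
#'   univariate sampler; vectorized `G0`/`R0` entries for the multi-trait
#'   sampler).
#' @slot traits character vector of trait names (length 1 for univariate).
#' @slot chain,burnIn,thin,seed the chain bookkeeping that produced the
#'   draws; `nrow(draws) == floor((chain - burnIn)/thin)`.
#' @export
setClass("PosteriorSamples",
  representation(draws = "matrix", traits = "character", chain = "numeric",
                 burnIn = "numeric", thin = "numeric", seed = "numeric")
)

setValidity("PosteriorSamples", function(object) {
  expect <- floor((object@chain - object@burnIn) / object@thin)
  if (nrow(object@draws) != expect) {
    return(sprintf("retained draws %d != floor((chain - burnIn)/thin) = %d",
                   nrow(object@draws), expect))
  }
  TRUE
})
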