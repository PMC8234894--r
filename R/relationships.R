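## Genomic relationship matrices and the single-step H-inverse.

#' Centered marker matrix
#'
#' `M = dosage - 2p`, the SNP content centered by twice the current allele
#' frequencies of the stored animals.
#'
#' @param g a [GenotypeData-class] (post-QC: no missing dosages).
#' @return numeric matrix, animals by SNPs, with (near-)zero column means.
#' @export
centeredDosages <- function(g) {
  X <- dosages(g)
  if (anyNA(X)) stop("missing dosages: run qcFilter() first")
  sweep(X, 2, 2 * snpFreqs(g), "-")
}

#' VanRaden genomic relationship matrix (plain or SNP-weighted)
#'
#' Method-1 VanRaden matrix `G = M D M' / (2 sum p_i (1 - p_i))` with
#' `M = dosage - 2p` and `D` the diagonal of per-SNP weights (identity for
#' the unweighted matrix).
#'
#' @param g a [GenotypeData-class].
#' @param weights `NULL` (unit weights), a numeric vector of positive
#'   per-SNP weights, or a [SnpWeights-class].
#' @return A [RelationshipMatrix-class] of kind `"G_RAW"`.
#' @export
vanRadenG <- function(g, weights = NULL) {
  M <- centeredDosages(g)
  p <- snpFreqs(g)
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all SNPs monomorphic: VanRaden denominator is zero")
  d <- if (is.null(weights)) rep(1, ncol(M)) else
    if (is(weights, "SnpWeights")) weights@d else as.numeric(weights)
  if (length(d) != ncol(M)) stop("weights length != number of SNPs")
  if (any(d <= 0)) stop("SNP weights must be positive")
  G <- tcrossprod(sweep(M, 2, d, "*"), M) / denom
  G <- (G + t(G)) / 2
  dimnames(G) <- list(animalIds(g), animalIds(g))
  new("RelationshipMatrix", kind = "G_RAW", matrix = G, ids = animalIds(g))
}

#' Tune G to the pedigree base of the genotyped animals
#'
#' Finds scalars (a, b) such that `a + b G` has the same mean diagonal and
#' mean off-diagonal as A22, making the genomic and pedigree relationships
#' compatible in base and scale. The 2x2 linear system is
#' `a + b mean(diag G) = mean(diag A22)`,
#' `a + b mean(offdiag G) = mean(offdiag A22)`.
#'
#' @param G a [RelationshipMatrix-class] (kind `G_RAW`).
#' @param A22 a [RelationshipMatrix-class] (kind `A22`), same ids.
#' @return A [RelationshipMatrix-class] of kind `"G_TUNED"`, with the fitted
#'   scalars in `attr(, "tuning")`.
#' @export
tuneG <- function(G, A22) {
  .checkSameIds(G, A22)
  Gm <- as.matrix(relMatrix(G))
  Am <- as.matrix(relMatrix(A22))
  n <- nrow(Gm)
  dG <- mean(diag(Gm))
  dA <- mean(diag(Am))
  if (n > 1) {
    oG <- (sum(Gm) - sum(diag(Gm))) / (n * n - n)
    oA <- (sum(Am) - sum(diag(Am))) / (n * n - n)
  } else {
    oG <- dG
    oA <- dA
  }
  if (abs(dG - oG) < 1e-12) {
    stop("degenerate tuning system: G has equal mean diagonal and ",
         "off-diagonal")
  }
  b <- (dA - oA) / (dG - oG)
  a <- dA - b * dG
  out <- a + b * Gm
  dimnames(out) <- dimnames(Gm)
  res <- new("RelationshipMatrix", kind = "G_TUNED", matrix = out,
             ids = animalIds(G))
  attr(res, "tuning") <- c(a = a, b = b)
  res
}

#' Blend G with A22 for invertibility
#'
#' `G_b = alpha G + beta A22` with the bending coefficients defaulting to
#' 0.95/0.05. The result is checked to be positive definite.
#'
#' @param G a [RelationshipMatrix-class] (typically kind `G_TUNED`).
#' @param A22 a [RelationshipMatrix-class] of kind `A22` on the same ids.
#' @param alpha,beta blending weights (default 0.95 and 0.05); a warning is
#'   given if they do not sum to 1.
#' @return A [RelationshipMatrix-class] of kind `"G_BLEND"`.
#' @export
blendG <- function(G, A22, alpha = 0.95, beta = 0.05) {
  .checkSameIds(G, A22)
  if (abs(alpha + beta - 1) > 1e-8) {
    warning("alpha + beta != 1 (", alpha + beta, ")")
  }
  Gb <- alpha * as.matrix(relMatrix(G)) + beta * as.matrix(relMatrix(A22))
  Gb <- (Gb + t(Gb)) / 2
  ev <- min(eigen(Gb, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0) {
    stop(sprintf("blended G not positive definite (min eigenvalue %.3e); ",
                 ev), "increase beta")
  }
  new("RelationshipMatrix", kind = "G_BLEND", matrix = Gb,
      ids = animalIds(G))
}

.checkSameIds <- function(x, y) {
  if (!identical(animalIds(x), animalIds(y))) {
    stop("relationship matrices are indexed by different animals")
  }
  if (!all(dim(relMatrix(x)) == dim(relMatrix(y)))) {
    stop("non-conformable relationship matrices")
  }
  invisible(TRUE)
}

#' Single-step H-inverse
#'
#' Assembles `H^-1 = A^-1 + [0 0; 0 Gb^-1 - A22^-1]` where the correction
#' block sits on the genotyped-by-genotyped submatrix and `Gb` is the
#' (tuned and) blended genomic matrix, i.e. the blend is applied inside the
#' inverse. Stored sparse; with no genotyped animals `H^-1 = A^-1`.
#'
#' @param Ainv a [RelationshipMatrix-class] of kind `A_INV` over the whole
#'   pedigree.
#' @param A22 a [RelationshipMatrix-class] of kind `A22` on the genotyped
#'   animals (ids must be a subset of `Ainv`'s).
#' @param Gblend a [RelationshipMatrix-class] of kind `G_BLEND` on the same
#'   genotyped animals, or `NULL` for the degenerate no-genomics case.
#' @return A [RelationshipMatrix-class] of kind `"H_INV"` (sparse).
#' @export
hInverse <- function(Ainv, A22 = NULL, Gblend = NULL) {
  H <- Matrix::Matrix(relMatrix(Ainv), sparse = TRUE)
  if (is.null(Gblend) || (!is.null(A22) && length(animalIds(A22)) == 0)) {
    return(new("RelationshipMatrix", kind = "H_INV", matrix = H,
               ids = animalIds(Ainv)))
  }
  if (is.null(A22)) stop("A22 required when genotyped animals are present")
  .checkSameIds(Gblend, A22)
  idx <- match(animalIds(A22), animalIds(Ainv))
  if (anyNA(idx)) stop("genotyped animals absent from the pedigree inverse")
  Gb <- as.matrix(relMatrix(Gblend))
  Ginv <- tryCatch(chol2inv(chol(Gb)), error = function(e)
    stop("singular blended G; blend with a larger beta (",
         conditionMessage(e), ")"))
  A22inv <- chol2inv(chol(as.matrix(relMatrix(A22))))
  corr <- (Ginv + t(Ginv)) / 2 - (A22inv + t(A22inv)) / 2
  H[idx, idx] <- H[idx, idx] + corr
  new("RelationshipMatrix", kind = "H_INV",
      matrix = Matrix::forceSymmetric(Matrix::drop0(H, tol = 0)),
      ids = animalIds(Ainv))
}

#' Build the single-step kernel inverse from the raw ingredients
#'
#' Convenience wrapper running the standard chain: A-inverse, A22 from the
#' genotyped ids, VanRaden G (optionally SNP-weighted), tuning to A22
#' (optional), blending, and the H-inverse.
#'
#' @param ped a [Pedigree-class].
#' @param g a [GenotypeData-class] or `NULL` (then the pedigree inverse is
#'   returned as the kernel).
#' @param weights optional per-SNP weights (see [vanRadenG()]).
#' @param alpha,beta blending coefficients (default 0.95/0.05).
#' @param tune logical: rescale G to A22's means first (default TRUE).
#' @return list with `Kinv` (kind `H_INV` or `A_INV`), plus `G`, `A22` when
#'   genotypes are used.
#' @export
buildKernel <- function(ped, g = NULL, weights = NULL, alpha = 0.95,
                        beta = 0.05, tune = TRUE) {
  Ainv <- makeAinverse(ped)
  if (is.null(g)) {
    return(list(Kinv = new("RelationshipMatrix", kind = "H_INV",
                           matrix = relMatrix(Ainv), ids = animalIds(Ainv)),
                G = NULL, A22 = NULL))
  }
  keep <- intersect(animalIds(ped), animalIds(g))
  if (length(keep) < nAnimals(g)) {
    stop("genotyped animals not in pedigree: ",
         paste(utils::head(setdiff(animalIds(g), keep), 5), collapse = ", "))
  }
  A22 <- makeA(ped, ids = animalIds(g))
  G <- vanRadenG(g, weights = weights)
  Gt <- if (tune) tuneG(G, A22) else G
  Gb <- blendG(Gt, A22, alpha = alpha, beta = beta)
  list(Kinv = hInverse(Ainv, A22, Gb), G = G, A22 = A22, Gblend = Gb)
}
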