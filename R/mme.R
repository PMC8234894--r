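## Design matrices and Henderson's mixed-model equations.

#' Design bundle for the single-trait animal model
#'
#' Builds `y = X b + Z a + e` ingredients from a phenotype table: `X` is
#' drop-first-level dummy coding of the categorical fixed effects with an
#' explicit intercept (unused levels dropped); `Z` maps records to pedigree
#' animal positions, so animals without records keep a column (and an EBV)
#' but contribute no row.
#'
#' @param phenotypes data.frame with columns `animal`, the trait, and the
#'   fixed-effect factors.
#' @param ped a [Pedigree-class]; every phenotyped animal must be in it.
#' @param trait name of the trait column.
#' @param fixed character vector of fixed-effect column names (default
#'   `contemporary_group` and `parity_class`).
#' @return list with `y`, `X` (dense), `Z` (sparse n_records x n_animals),
#'   `recordIds`, `animalIds`, `trait`, `fixed`.
#' @export
buildDesign <- function(phenotypes, ped, trait,
                        fixed = c("contemporary_group", "parity_class")) {
  stopifnot(is.data.frame(phenotypes), "animal" %in% names(phenotypes))
  if (!trait %in% names(phenotypes)) {
    stop("trait column '", trait, "' not in phenotype table")
  }
  miss <- setdiff(fixed, names(phenotypes))
  if (length(miss)) {
    stop("fixed effect column(s) missing: ", paste(miss, collapse = ", "))
  }
  keep <- !is.na(phenotypes[[trait]])
  ph <- phenotypes[keep, , drop = FALSE]
  pos <- match(as.character(ph$animal), animalIds(ped))
  if (anyNA(pos)) {
    stop("phenotyped animal(s) not in pedigree: ",
         paste(utils::head(ph$animal[is.na(pos)], 5), collapse = ", "))
  }
  nrec <- nrow(ph)
  ff <- lapply(fixed, function(f) droplevels(factor(ph[[f]])))
  names(ff) <- fixed
  keepEff <- vapply(ff, function(f) nlevels(f) > 1, logical(1))
  if (length(ff) && any(keepEff)) {
    X <- stats::model.matrix(
      ~ ., data = as.data.frame(ff[keepEff], check.names = FALSE))
  } else {
    X <- matrix(1, nrec, 1, dimnames = list(NULL, "(Intercept)"))
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("fixed part rank-deficient after drop-first coding; confounded ",
         "columns: ",
         paste(colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]],
               collapse = ", "))
  }
  Z <- Matrix::sparseMatrix(i = seq_len(nrec), j = pos, x = 1,
                            dims = c(nrec, nAnimals(ped)),
                            dimnames = list(NULL, animalIds(ped)))
  list(y = as.numeric(ph[[trait]]), X = X, Z = Z,
       recordIds = as.character(ph$animal), animalIds = animalIds(ped),
       trait = trait, fixed = fixed)
}

#' Solve Henderson's mixed-model equations
#'
#' Solves
#' \deqn{\begin{bmatrix} X'X & X'Z \\ Z'X & Z'Z + \lambda K^{-1}
#' \end{bmatrix}\begin{bmatrix}\hat b\\ \hat a\end{bmatrix} =
#' \begin{bmatrix}X'y\\ Z'y\end{bmatrix}}
#' with \eqn{\lambda = \sigma_e^2/\sigma_a^2} by sparse Cholesky
#' factorization, falling back to the sparse LU if the Cholesky fails. The
#' relative residual of the normal equations is checked against `tol`.
#'
#' @param design a bundle from [buildDesign()].
#' @param Kinv a [RelationshipMatrix-class] of kind `A_INV` or `H_INV`
#'   covering all pedigree animals (same ids and order as the design).
#' @param sigmaA2,sigmaE2 additive-genetic and residual variances; or pass
#'   `lambda` directly.
#' @param lambda variance ratio \eqn{\sigma_e^2/\sigma_a^2}; overrides the
#'   two variances if given.
#' @param modelTag,datasetTag labels stored in the result.
#' @param tol relative residual tolerance (default 1e-8).
#' @return A [SolutionSet-class].
#' @export
solveMME <- function(design, Kinv, sigmaA2 = NULL, sigmaE2 = NULL,
                     lambda = NULL, modelTag = "BLUP", datasetTag = "WHOLE",
                     tol = 1e-8) {
  if (is.null(lambda)) {
    if (is.null(sigmaA2) || is.null(sigmaE2)) {
      stop("supply lambda or both sigmaA2 and sigmaE2")
    }
    lambda <- sigmaE2 / sigmaA2
  }
  if (lambda <= 0) stop("lambda must be positive")
  if (!identical(animalIds(Kinv), design$animalIds)) {
    stop("kernel inverse and design indexed by different animals")
  }
  C <- .mmeCoef(design, relMatrix(Kinv), lambda)
  p <- ncol(design$X)
  rhs <- c(crossprod(design$X, design$y),
           as.numeric(Matrix::crossprod(design$Z, design$y)))
  sol <- tryCatch({
    ch <- Matrix::Cholesky(C, LDL = FALSE, super = NA)
    as.numeric(Matrix::solve(ch, rhs))
  }, error = function(e) as.numeric(Matrix::solve(C, rhs)))
  resid <- sqrt(sum((as.numeric(C %*% sol) - rhs)^2))
  converged <- resid <= tol * max(sqrt(sum(rhs^2)), 1e-300)
  if (!converged) {
    warning(sprintf("MME residual %.3e above tolerance", resid))
  }
  b <- sol[seq_len(p)]
  a <- sol[-seq_len(p)]
  names(a) <- design$animalIds
  fx <- data.frame(effect = .effectOfColumn(colnames(design$X), design$fixed),
                   level = colnames(design$X), estimate = b)
  new("SolutionSet", fixed = fx, ebv = a, modelTag = modelTag,
      datasetTag = datasetTag, converged = converged)
}

.effectOfColumn <- function(nm, fixed) {
  out <- rep("intercept", length(nm))
  for (f in fixed[order(nchar(fixed), decreasing = TRUE)]) {
    hit <- out == "intercept" & startsWith(nm, f)
    out[hit] <- f
  }
  out
}

## sparse symmetric MME coefficient matrix for a given lambda
.mmeCoef <- function(design, KinvM, lambda) {
  X <- Matrix::Matrix(design$X, sparse = TRUE)
  Z <- design$Z
  C <- rbind(
    cbind(Matrix::crossprod(X), Matrix::crossprod(X, Z)),
    cbind(Matrix::crossprod(Z, X),
          Matrix::crossprod(Z) + lambda * Matrix::Matrix(KinvM,
                                                         sparse = TRUE)))
  Matrix::forceSymmetric(C)
}

#' Run one evaluation model end to end
#'
#' Orchestrates kernel construction and the MME solve for one trait:
#' `"PBLUP"` uses the pedigree inverse; `"ssGBLUP"` the single-step
#' H-inverse (VanRaden G, tuned and blended); `"WssGBLUP"` the same with
#' per-SNP weights (which must be supplied — the iterative loop lives in
#' [wssgblup()]).
#'
#' @param data list with elements `ped` ([Pedigree-class]), `phenotypes`
#'   (data.frame) and, for genomic methods, `genotypes`
#'   ([GenotypeData-class]).
#' @param trait trait column name.
#' @param method `"PBLUP"`, `"ssGBLUP"` or `"WssGBLUP"`.
#' @param sigmaA2,sigmaE2,lambda variance components (see [solveMME()]).
#' @param weights per-SNP weights, required for `"WssGBLUP"`.
#' @param fixed fixed-effect columns (see [buildDesign()]).
#' @param alpha,beta,tune kernel options (see [buildKernel()]).
#' @param datasetTag label stored in the result.
#' @return A [SolutionSet-class]; the kernel pieces are attached as
#'   `attr(, "kernel")`.
#' @export
runModel <- function(data, trait, method = c("PBLUP", "ssGBLUP", "WssGBLUP"),
                     sigmaA2 = NULL, sigmaE2 = NULL, lambda = NULL,
                     weights = NULL,
                     fixed = c("contemporary_group", "parity_class"),
                     alpha = 0.95, beta = 0.05, tune = TRUE,
                     datasetTag = "WHOLE") {
  method <- match.arg(method)
  g <- data$genotypes
  if (method == "PBLUP") g <- NULL
  if (method != "PBLUP" && is.null(g)) {
    stop(method, " requires genotypes")
  }
  if (method == "WssGBLUP" && is.null(weights)) {
    stop("WssGBLUP requires SNP weights; use wssgblup() for the ",
         "iterative algorithm")
  }
  design <- buildDesign(data$phenotypes, data$ped, trait, fixed = fixed)
  if (method == "PBLUP") {
    kern <- list(Kinv = makeAinverse(data$ped), G = NULL, A22 = NULL)
    Kinv <- kern$Kinv
  } else {
    kern <- buildKernel(data$ped, g,
                        weights = if (method == "WssGBLUP") weights else NULL,
                        alpha = alpha, beta = beta, tune = tune)
    Kinv <- kern$Kinv
  }
  sol <- solveMME(design, Kinv, sigmaA2 = sigmaA2, sigmaE2 = sigmaE2,
                  lambda = lambda, modelTag = method,
                  datasetTag = datasetTag)
  attr(sol, "kernel") <- kern
  sol
}
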