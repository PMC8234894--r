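## Gibbs sampling of variance components for the animal model.
##
## Location parameters are sampled jointly from their multivariate-normal
## full conditional through a sparse Cholesky factor of the MME coefficient
## matrix (symbolic analysis reused across iterations); variances come from
## scaled inverse chi-square (univariate) or inverse-Wishart (multi-trait)
## full conditionals.

#' Number of retained Gibbs draws
#'
#' `floor((chain - burnIn)/thin)`: the draw count every sampler in the
#' package stores (the long-chain preset 200000/5000/100 retains 1950).
#'
#' @param chain,burnIn,thin chain settings.
#' @return integer count of retained draws.
#' @export
retainedDraws <- function(chain, burnIn, thin) {
  stopifnot(burnIn < chain, thin >= 1)
  as.integer(floor((chain - burnIn) / thin))
}

## sample x ~ N(C^-1 rhs, C^-1 * scale) given an updated CHMfactor of C
.sampleLocation <- function(ch, rhs, scale = 1) {
  mu <- as.numeric(Matrix::solve(ch, rhs))
  z <- stats::rnorm(length(rhs))
  pert <- as.numeric(Matrix::solve(ch, Matrix::solve(ch, z, system = "Lt"),
                                   system = "Pt"))
  mu + sqrt(scale) * pert
}

#' Univariate Gibbs sampler for the animal model
#'
#' Standard single-trait animal-model Gibbs sampler: `(b, a)` drawn jointly
#' from their normal full conditional via a sparse Cholesky of the MME
#' coefficient matrix; \eqn{\sigma^2_a} from a scaled inverse chi-square
#' using the quadratic form \eqn{a'K^{-1}a}; \eqn{\sigma^2_e} from the
#' residual sum of squares. Default priors are flat on both variances
#' (degrees of freedom -2, scale 0).
#'
#' @param design bundle from [buildDesign()].
#' @param Kinv a [RelationshipMatrix-class] (`A_INV` or `H_INV`) over the
#'   design's animals.
#' @param chain total iterations; `burnIn` discarded; every `thin`-th kept.
#'   `floor((chain - burnIn)/thin)` draws are retained — the long-chain
#'   preset 200000/5000/100 retains 1950.
#' @param burnIn,thin see `chain`.
#' @param seed integer seed; identical seed and data give identical chains.
#' @param nuA,scaleA,nuE,scaleE scaled-inverse-chi-square prior df and scale
#'   for the genetic and residual variances (defaults: flat).
#' @param start optional list with `sigma2_a`, `sigma2_e` starting values.
#' @return A [PosteriorSamples-class] with columns `sigma2_a`, `sigma2_e`.
#' @export
gibbsUnivariate <- function(design, Kinv, chain = 20000, burnIn = 2000,
                            thin = 10, seed = 1, nuA = -2, scaleA = 0,
                            nuE = -2, scaleE = 0, start = NULL) {
  stopifnot(burnIn < chain, thin >= 1)
  if (!identical(animalIds(Kinv), design$animalIds)) {
    stop("kernel inverse and design indexed by different animals")
  }
  set.seed(seed)
  y <- design$y
  X <- Matrix::Matrix(design$X, sparse = TRUE)
  Z <- design$Z
  n <- length(y)
  p <- ncol(X)
  q <- ncol(Z)
  KM <- Matrix::Matrix(relMatrix(Kinv), sparse = TRUE)
  W <- cbind(X, Z)
  WtW <- Matrix::forceSymmetric(Matrix::crossprod(W))
  Kaug <- Matrix::bdiag(Matrix::Matrix(0, p, p, sparse = TRUE), KM)
  Wty <- as.numeric(Matrix::crossprod(W, y))

  vy <- stats::var(y)
  s2a <- if (is.null(start$sigma2_a)) vy / 2 else start$sigma2_a
  s2e <- if (is.null(start$sigma2_e)) vy / 2 else start$sigma2_e

  C <- Matrix::forceSymmetric(WtW + (s2e / s2a) * Kaug)
  ch <- Matrix::Cholesky(C, LDL = FALSE, super = NA)

  nKeep <- retainedDraws(chain, burnIn, thin)
  draws <- matrix(NA_real_, nKeep, 2,
                  dimnames = list(NULL, c("sigma2_a", "sigma2_e")))
  k <- 0
  for (it in seq_len(chain)) {
    C <- Matrix::forceSymmetric(WtW + (s2e / s2a) * Kaug)
    ch <- Matrix::update(ch, C)
    theta <- .sampleLocation(ch, Wty, scale = s2e)
    a <- theta[(p + 1):(p + q)]
    qf <- as.numeric(Matrix::crossprod(a, KM %*% a))
    s2a <- (qf + nuA * scaleA) / stats::rchisq(1, df = q + nuA)
    e <- y - as.numeric(W %*% theta)
    s2e <- (sum(e * e) + nuE * scaleE) / stats::rchisq(1, df = n + nuE)
    if (it > burnIn && (it - burnIn) %% thin == 0) {
      k <- k + 1
      draws[k, ] <- c(s2a, s2e)
    }
  }
  new("PosteriorSamples", draws = draws, traits = design$trait,
      chain = chain, burnIn = burnIn, thin = thin, seed = seed)
}

#' Multi-trait Gibbs sampler for the animal model
#'
#' Samples the genetic covariance matrix G0 and residual covariance R0 of a
#' multi-trait animal model with covariance structures
#' \eqn{G_0 \otimes A} and \eqn{R_0 \otimes I}, from inverse-Wishart full
#' conditionals; all location parameters are drawn jointly. Records must be
#' complete (every phenotyped animal scored for every trait).
#'
#' @param phenotypes data.frame with `animal`, the trait columns and the
#'   fixed-effect factors.
#' @param ped a [Pedigree-class].
#' @param traits character vector (>= 2) of trait column names.
#' @param Kinv a [RelationshipMatrix-class]; defaults to the pedigree
#'   inverse of `ped`.
#' @param fixed fixed-effect columns.
#' @param chain,burnIn,thin,seed chain settings (see [gibbsUnivariate()]).
#' @param priorDf inverse-Wishart prior degrees of freedom; the default
#'   `-(length(traits) + 1)` with a zero scale is the flat prior on the
#'   covariance matrix, the analog of the univariate flat variance prior.
#' @param priorScale prior scale matrix (default: zero matrix).
#' @return A [PosteriorSamples-class]; columns are the vectorized lower
#'   triangles of G0 and R0 (`G0_t1_t2`, `R0_t1_t2`).
#' @export
gibbsMultitrait <- function(phenotypes, ped, traits, Kinv = NULL,
                            fixed = c("contemporary_group", "parity_class"),
                            chain = 10000, burnIn = 1000, thin = 5,
                            seed = 1, priorDf = NULL, priorScale = NULL) {
  nt <- length(traits)
  if (nt < 2) stop("multi-trait sampler needs at least 2 traits")
  stopifnot(burnIn < chain, thin >= 1)
  complete <- stats::complete.cases(phenotypes[, c("animal", traits, fixed)])
  ph <- phenotypes[complete, , drop = FALSE]
  designs <- lapply(traits, function(tr) buildDesign(ph, ped, tr, fixed))
  X <- designs[[1]]$X
  Z <- designs[[1]]$Z
  Y <- vapply(designs, `[[`, numeric(nrow(X)), "y")
  if (is.null(Kinv)) Kinv <- makeAinverse(ped)
  KM <- Matrix::Matrix(relMatrix(Kinv), sparse = TRUE)
  set.seed(seed)
  n <- nrow(Y)
  p <- ncol(X)
  q <- ncol(Z)
  ## default: flat prior on each covariance matrix (the multivariate
  ## analog of the univariate flat variance prior nu = -2): density
  ## proportional to 1, i.e. inverse-Wishart df -(t+1) and zero scale.
  ## Informative alternatives are strongly felt here: a small-scale
  ## diffuse IW favors singular G0 (correlations pile at +-1), a diagonal
  ## data-scale prior shrinks correlations toward 0.
  if (is.null(priorDf)) priorDf <- -(nt + 1)
  if (is.null(priorScale)) priorScale <- matrix(0, nt, nt)

  W <- cbind(Matrix::Matrix(X, sparse = TRUE), Z)
  WtW <- Matrix::forceSymmetric(Matrix::crossprod(W))
  Kaug <- Matrix::bdiag(Matrix::Matrix(0, p, p, sparse = TRUE), KM)
  WtY <- as.matrix(Matrix::crossprod(W, Y))

  S0 <- stats::cov(Y)
  G0 <- S0 / 2
  R0 <- S0 / 2
  ch <- NULL
  nKeep <- retainedDraws(chain, burnIn, thin)
  parNames <- c(outer(seq_len(nt), seq_len(nt), function(i, j)
    sprintf("G0_%d_%d", i, j))[lower.tri(G0, diag = TRUE)],
    outer(seq_len(nt), seq_len(nt), function(i, j)
      sprintf("R0_%d_%d", i, j))[lower.tri(R0, diag = TRUE)])
  draws <- matrix(NA_real_, nKeep, length(parNames),
                  dimnames = list(NULL, parNames))
  k <- 0
  for (it in seq_len(chain)) {
    R0inv <- chol2inv(chol(R0))
    G0inv <- chol2inv(chol(G0))
    C <- Matrix::forceSymmetric(
      kronecker(R0inv, WtW) + kronecker(G0inv, Kaug))
    ch <- if (is.null(ch)) Matrix::Cholesky(C, LDL = FALSE, super = NA)
          else Matrix::update(ch, C)
    rhs <- as.numeric(WtY %*% R0inv)
    theta <- .sampleLocation(ch, rhs, scale = 1)
    Theta <- matrix(theta, ncol = nt)
    U <- Theta[(p + 1):(p + q), , drop = FALSE]
    Sg <- as.matrix(Matrix::crossprod(U, KM %*% U))
    G0 <- .rinvwishart(priorDf + q, priorScale + Sg)
    E <- Y - as.matrix(W %*% Theta)
    Se <- crossprod(E)
    R0 <- .rinvwishart(priorDf + n, priorScale + Se)
    if (it > burnIn && (it - burnIn) %% thin == 0) {
      k <- k + 1
      draws[k, ] <- c(G0[lower.tri(G0, diag = TRUE)],
                      R0[lower.tri(R0, diag = TRUE)])
    }
  }
  new("PosteriorSamples", draws = draws, traits = traits, chain = chain,
      burnIn = burnIn, thin = thin, seed = seed)
}

.rinvwishart <- function(df, S) {
  Sinv <- chol2inv(chol((S + t(S)) / 2))
  Wdraw <- stats::rWishart(1, df, (Sinv + t(Sinv)) / 2)[, , 1]
  out <- chol2inv(chol(Wdraw))
  (out + t(out)) / 2
}

#' Posterior summaries: means, HPD intervals, heritability, correlations
#'
#' Computes, per retained draw, the derived quantities — heritability
#' \eqn{h^2 = \sigma^2_a/(\sigma^2_a + \sigma^2_e)} for each trait, and
#' genetic/residual correlations \eqn{r = cov/\sqrt{v_1 v_2}} for each trait
#' pair in the multi-trait case — then reports the posterior mean and the
#' 95% highest-posterior-density interval of every raw and derived
#' parameter. The HPD interval is the shortest window on the sorted draws.
#'
#' @param s a [PosteriorSamples-class] with at least 30 retained draws.
#' @param prob HPD mass (default 0.95).
#' @return data.frame with columns `parameter`, `mean`, `lower`, `upper`.
#' @export
posteriorSummary <- function(s, prob = 0.95) {
  stopifnot(is(s, "PosteriorSamples"))
  D <- s@draws
  if (nrow(D) < 30) stop("too few retained draws (", nrow(D), " < 30)")
  nt <- length(s@traits)
  derived <- list()
  if (ncol(D) == 2 && all(c("sigma2_a", "sigma2_e") %in% colnames(D))) {
    derived$h2 <- D[, "sigma2_a"] / (D[, "sigma2_a"] + D[, "sigma2_e"])
  } else {
    for (t in seq_len(nt)) {
      g <- D[, sprintf("G0_%d_%d", t, t)]
      r <- D[, sprintf("R0_%d_%d", t, t)]
      derived[[sprintf("h2_%s", s@traits[t])]] <- g / (g + r)
    }
    if (nt >= 2) {
      for (i in seq_len(nt - 1)) for (j in (i + 1):nt) {
        cg <- D[, sprintf("G0_%d_%d", j, i)]
        derived[[sprintf("rg_%s_%s", s@traits[i], s@traits[j])]] <-
          cg / sqrt(D[, sprintf("G0_%d_%d", i, i)] *
                    D[, sprintf("G0_%d_%d", j, j)])
        cr <- D[, sprintf("R0_%d_%d", j, i)]
        derived[[sprintf("re_%s_%s", s@traits[i], s@traits[j])]] <-
          cr / sqrt(D[, sprintf("R0_%d_%d", i, i)] *
                    D[, sprintf("R0_%d_%d", j, j)])
      }
    }
  }
  all <- cbind(D, do.call(cbind, derived))
  out <- data.frame(
    parameter = colnames(all),
    mean = colMeans(all),
    t(apply(all, 2, hpdInterval, prob = prob)))
  names(out)[3:4] <- c("lower", "upper")
  rownames(out) <- NULL
  out
}

#' Shortest (highest-density) posterior interval
#'
#' Scans the sorted draws for the shortest window containing
#' `ceiling(prob * n)` of them.
#'
#' @param x numeric draws.
#' @param prob interval mass (default 0.95).
#' @return numeric `c(lower, upper)`.
#' @export
hpdInterval <- function(x, prob = 0.95) {
  x <- sort(x)
  n <- length(x)
  m <- min(n, ceiling(prob * n))
  if (m == n) return(c(x[1], x[n]))
  starts <- seq_len(n - m + 1)
  widths <- x[starts + m - 1] - x[starts]
  i <- which.min(widths)
  c(x[i], x[i + m - 1])
}
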