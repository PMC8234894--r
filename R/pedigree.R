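## Pedigree ingestion and numerator-relationship algebra.
##
## All recursions assume a topologically sorted pedigree (parents before
## offspring), which the constructor enforces with a stable generation-depth
## sort, so downstream code can run single forward passes.

#' Build a validated, sorted Pedigree
#'
#' Normalizes unknown-parent tokens, auto-adds parents that appear only in the
#' sire/dam columns as founders (with a warning), rejects duplicated ids and
#' parent cycles, and topologically sorts the records by generation depth
#' (ties broken by input order, so the result is reproducible).
#'
#' @param animal character vector of animal ids.
#' @param sire,dam character vectors of parent ids; `unknown` tokens and `NA`
#'   mark an unknown parent.
#' @param birthYear integer birth years (optional, `NA` allowed).
#' @param sex character `"M"`/`"F"` (optional).
#' @param unknown character tokens to treat as "parent unknown"
#'   (default `"0"` and the empty string).
#' @return A [Pedigree-class].
#' @examples
#' ped <- Pedigree(c("A", "B", "X"), c("0", "0", "A"), c("0", "0", "B"))
#' inbreeding(ped)
#' @export
Pedigree <- function(animal, sire, dam, birthYear = NA_integer_,
                     sex = NA_character_, unknown = c("0", "")) {
  animal <- as.character(animal)
  sire <- as.character(sire)
  dam <- as.character(dam)
  if (anyDuplicated(animal)) {
    stop("duplicate animal id: '", animal[duplicated(animal)][1], "'")
  }
  norm <- function(x) {
    x[is.na(x) | x %in% unknown] <- NA_character_
    x
  }
  sire <- norm(sire)
  dam <- norm(dam)
  if (any(!is.na(sire) & sire == animal) || any(!is.na(dam) & dam == animal)) {
    bad <- animal[(!is.na(sire) & sire == animal) |
                  (!is.na(dam) & dam == animal)][1]
    stop("pedigree cycle: animal '", bad, "' is its own parent")
  }
  missingParents <- setdiff(c(sire, dam), c(animal, NA_character_))
  if (length(missingParents)) {
    warning(length(missingParents),
            " parent(s) absent from the file added as founders: ",
            paste(utils::head(missingParents, 5), collapse = ", "),
            if (length(missingParents) > 5) ", ..." else "")
    animal <- c(animal, missingParents)
    sire <- c(sire, rep(NA_character_, length(missingParents)))
    dam <- c(dam, rep(NA_character_, length(missingParents)))
    birthYear <- c(rep_len(as.integer(birthYear), length(animal) -
                           length(missingParents)),
                   rep(NA_integer_, length(missingParents)))
    sex <- c(rep_len(as.character(sex), length(animal) -
                     length(missingParents)),
             rep(NA_character_, length(missingParents)))
  } else {
    birthYear <- rep_len(as.integer(birthYear), length(animal))
    sex <- rep_len(as.character(sex), length(animal))
  }
  n <- length(animal)
  si <- match(sire, animal)
  di <- match(dam, animal)

  ## generation depth with cycle detection (iterative DFS, colors 0/1/2)
  depth <- rep(NA_integer_, n)
  state <- integer(n)  # 0 = unseen, 1 = on stack, 2 = done
  for (root in seq_len(n)) {
    if (state[root] == 2L) next
    stack <- root
    while (length(stack)) {
      v <- stack[length(stack)]
      if (state[v] == 2L) {
        stack <- stack[-length(stack)]
        next
      }
      parents <- c(si[v], di[v])
      parents <- parents[!is.na(parents)]
      pending <- parents[state[parents] != 2L]
      if (length(pending)) {
        if (any(state[pending] == 1L)) {
          cyc <- animal[pending[state[pending] == 1L][1]]
          stop("pedigree cycle detected involving '", cyc, "'")
        }
        state[v] <- 1L
        stack <- c(stack, pending)
      } else {
        depth[v] <- if (length(parents)) max(depth[parents]) + 1L else 0L
        state[v] <- 2L
        stack <- stack[-length(stack)]
      }
    }
  }
  o <- order(depth, seq_len(n))  # stable: ties by input order
  rank <- integer(n)
  rank[o] <- seq_len(n)
  new("Pedigree",
      id = animal[o],
      sire = ifelse(is.na(si[o]), NA_integer_, rank[si[o]]),
      dam = ifelse(is.na(di[o]), NA_integer_, rank[di[o]]),
      birthYear = birthYear[o],
      sex = sex[o])
}

#' Read a pedigree CSV
#'
#' Expects a header with (by default) columns `animal`, `sire`, `dam` and
#' optionally `birth_year` and `sex`. Column names can be remapped through
#' `dialect`. Unknown-parent tokens are normalized, parents missing from the
#' file are auto-added as founders with a warning, and the result is
#' topologically sorted.
#'
#' @param path path to a CSV file.
#' @param dialect named list remapping the default column names, e.g.
#'   `list(animal = "id", sire = "father")`.
#' @param unknown tokens marking an unknown parent (default `"0"`, `""`).
#' @return A [Pedigree-class].
#' @examples
#' # a small synthetic pedigree shipped with the package
#' ped <- readPedigree(system.file("extdata", "example_pedigree.csv",
#'                                 package = "singlestep"))
#' ped
#' inbreeding(ped)
#' @export
readPedigree <- function(path, dialect = list(), unknown = c("0", "")) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  cols <- list(animal = "animal", sire = "sire", dam = "dam",
               birth_year = "birth_year", sex = "sex")
  cols[names(dialect)] <- dialect
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, strip.white = TRUE)
  need <- unlist(cols[c("animal", "sire", "dam")])
  if (!all(need %in% names(df))) {
    stop("pedigree file lacks required column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  by <- if (cols$birth_year %in% names(df)) {
    suppressWarnings(as.integer(df[[cols$birth_year]]))
  } else NA_integer_
  sx <- if (cols$sex %in% names(df)) df[[cols$sex]] else NA_character_
  Pedigree(df[[cols$animal]], df[[cols$sire]], df[[cols$dam]],
           birthYear = by, sex = sx, unknown = unknown)
}

## Mendelian-sampling variance d_i given parent inbreeding, with the
## unknown-parent convention F(unknown) = -1:
##   both known  -> 0.5 - 0.25 (F_s + F_d)
##   one known   -> 0.75 - 0.25 F_known
##   none known  -> 1
.mendelianD <- function(ped, F) {
  Fs <- ifelse(is.na(ped@sire), -1, F[ped@sire])
  Fd <- ifelse(is.na(ped@dam), -1, F[ped@dam])
  0.5 - 0.25 * (Fs + Fd)
}

#' @describeIn inbreeding Meuwissen-Luo linear-time recursion: for each
#'   animal the diagonal of A is accumulated by tracing the L-row over its
#'   ancestors only, never forming A. Animals sharing both parents are
#'   computed once. Founders and animals with an unknown parent get F = 0.
setMethod("inbreeding", "Pedigree", function(ped, ...) {
  n <- length(ped@id)
  F <- numeric(n)
  if (n == 0) return(F)
  D <- numeric(n)
  cache <- new.env(hash = TRUE, parent = emptyenv())
  L <- numeric(n)
  for (i in seq_len(n)) {
    s <- ped@sire[i]
    d <- ped@dam[i]
    D[i] <- 0.5 - 0.25 * ((if (is.na(s)) -1 else F[s]) +
                          (if (is.na(d)) -1 else F[d]))
    if (is.na(s) || is.na(d)) {
      F[i] <- 0
      next
    }
    key <- paste0(s, "_", d)
    hit <- cache[[key]]
    if (!is.null(hit)) {
      F[i] <- hit
      next
    }
    ## trace a_ii = sum_j L_ij^2 D_j over ancestors j of i
    L[i] <- 1
    touched <- i
    aii <- 0
    for (j in i:1) {
      lj <- L[j]
      if (lj == 0) next
      aii <- aii + lj * lj * D[j]
      js <- ped@sire[j]
      jd <- ped@dam[j]
      if (!is.na(js)) {
        if (L[js] == 0) touched <- c(touched, js)
        L[js] <- L[js] + 0.5 * lj
      }
      if (!is.na(jd)) {
        if (L[jd] == 0) touched <- c(touched, jd)
        L[jd] <- L[jd] + 0.5 * lj
      }
    }
    L[touched] <- 0
    ## a_ii for animal i itself uses D_i with its *own* parents known, so
    ## aii = 1 + F_i only after the full trace; equivalently F_i = aii - 1.
    F[i] <- aii - 1
    cache[[key]] <- F[i]
  }
  names(F) <- ped@id
  F
})

#' Numerator relationship matrix (tabular method)
#'
#' Builds the pedigree (IBD) relationship matrix A by the tabular recursion
#' `a_ij = 0.5 (a_{j,sire(i)} + a_{j,dam(i)})`, `a_ii = 1 + 0.5 a_{sire,dam}`.
#' For a subset of ids the full matrix is never formed: each required column
#' is obtained by Colleau's indirect method (two triangular passes through
#' the sorted pedigree), so genotyped-subset blocks scale to large pedigrees.
#'
#' @param ped a [Pedigree-class].
#' @param ids animal ids giving the rows/columns of the result; `NULL`
#'   (default) means all animals.
#' @return A [RelationshipMatrix-class] of kind `"A"` (or `"A22"` when `ids`
#'   is a proper subset).
#' @export
makeA <- function(ped, ids = NULL) {
  n <- length(ped@id)
  subset <- !is.null(ids)
  if (subset) {
    idx <- match(ids, ped@id)
    if (length(idx) == 0) stop("empty id set")
    if (anyNA(idx)) {
      stop("ids not in pedigree: ",
           paste(ids[is.na(idx)][seq_len(min(5, sum(is.na(idx))))],
                 collapse = ", "))
    }
    if (anyDuplicated(idx)) stop("duplicated ids would make A22 singular")
  } else {
    idx <- seq_len(n)
  }
  if (!subset || length(idx) > 0.5 * n || n <= 200) {
    A <- .tabularA(ped)
    M <- A[idx, idx, drop = FALSE]
  } else {
    F <- inbreeding(ped)
    D <- .mendelianD(ped, F)
    M <- matrix(0, length(idx), length(idx))
    for (k in seq_along(idx)) {
      col <- .colleauAv(ped, D, idx[k])
      M[, k] <- col[idx]
    }
    M <- (M + t(M)) / 2
  }
  dimnames(M) <- list(ped@id[idx], ped@id[idx])
  new("RelationshipMatrix",
      kind = if (subset && length(idx) < n) "A22" else "A",
      matrix = M, ids = ped@id[idx])
}

## dense tabular A over the whole (sorted) pedigree
.tabularA <- function(ped) {
  n <- length(ped@id)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- ped@sire[i]
    d <- ped@dam[i]
    if (i > 1) {
      j <- seq_len(i - 1)
      r <- numeric(i - 1)
      if (!is.na(s)) r <- r + 0.5 * A[j, s]
      if (!is.na(d)) r <- r + 0.5 * A[j, d]
      A[j, i] <- r
      A[i, j] <- r
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  A
}

## Colleau (2002) indirect product: A e_k = T D T' e_k with
## T = (I - P)^{-1} the gene-flow operator; two O(n) passes.
.colleauAv <- function(ped, D, k) {
  n <- length(ped@id)
  w <- numeric(n)
  w[k] <- 1
  for (j in n:1) {             # w = T' e_k (upward pass)
    wj <- w[j]
    if (wj == 0) next
    if (!is.na(ped@sire[j])) w[ped@sire[j]] <- w[ped@sire[j]] + 0.5 * wj
    if (!is.na(ped@dam[j]))  w[ped@dam[j]]  <- w[ped@dam[j]]  + 0.5 * wj
  }
  z <- D * w                   # z = D w
  for (j in seq_len(n)) {      # z <- T z (downward pass)
    s <- ped@sire[j]
    d <- ped@dam[j]
    if (!is.na(s)) z[j] <- z[j] + 0.5 * z[s]
    if (!is.na(d)) z[j] <- z[j] + 0.5 * z[d]
  }
  z
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Builds A-inverse directly by Henderson's rules with inbreeding-corrected
#' Mendelian-sampling variances (never by inverting a dense A). Each animal
#' contributes at most nine nonzeros: `b_i` on its own diagonal, `-b_i/2` to
#' the animal-parent cells and `b_i/4` among the parents, where
#' `b_i = 1/d_i` and `d_i = 0.5 - 0.25 (F_sire + F_dam)` (unknown parents
#' enter with F = -1).
#'
#' @param ped a [Pedigree-class].
#' @return A [RelationshipMatrix-class] of kind `"A_INV"` (sparse).
#' @export
makeAinverse <- function(ped) {
  n <- length(ped@id)
  F <- inbreeding(ped)
  b <- 1 / .mendelianD(ped, F)
  ii <- jj <- integer(0)
  xx <- numeric(0)
  s <- ped@sire
  d <- ped@dam
  idx <- seq_len(n)
  add <- function(i, j, x) {
    ii <<- c(ii, i)
    jj <<- c(jj, j)
    xx <<- c(xx, x)
  }
  add(idx, idx, b)
  ks <- which(!is.na(s))
  kd <- which(!is.na(d))
  kb <- which(!is.na(s) & !is.na(d))
  if (length(ks)) {
    add(ks, s[ks], -b[ks] / 2)
    add(s[ks], ks, -b[ks] / 2)
    add(s[ks], s[ks], b[ks] / 4)
  }
  if (length(kd)) {
    add(kd, d[kd], -b[kd] / 2)
    add(d[kd], kd, -b[kd] / 2)
    add(d[kd], d[kd], b[kd] / 4)
  }
  if (length(kb)) {
    add(s[kb], d[kb], b[kb] / 4)
    add(d[kb], s[kb], b[kb] / 4)
  }
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(ped@id, ped@id))
  new("RelationshipMatrix", kind = "A_INV",
      matrix = Matrix::drop0(Ainv), ids = ped@id)
}

#' Pedigree relationship block of the genotyped animals
#'
#' Extracts A22, the numerator-relationship submatrix of the genotyped
#' animals (via [makeA()], which uses Colleau's indirect method for small
#' subsets of large pedigrees), and inverts it densely. The inverse is
#' computed from A22 itself, not by subsetting the sparse A-inverse, whose
#' genotyped block is a different matrix.
#'
#' @param ped a [Pedigree-class].
#' @param genotypedIds ids of the genotyped animals (subset of the pedigree).
#' @return list with elements `A22` and `A22inv`
#'   ([RelationshipMatrix-class] of kinds `"A22"`, `"A22_INV"`).
#' @export
makeA22 <- function(ped, genotypedIds) {
  A22 <- makeA(ped, ids = genotypedIds)
  M <- relMatrix(A22)
  inv <- tryCatch(chol2inv(chol(M)),
                  error = function(e) stop("A22 is singular: ",
                                           conditionMessage(e)))
  inv <- (inv + t(inv)) / 2
  dimnames(inv) <- dimnames(M)
  list(A22 = A22,
       A22inv = new("RelationshipMatrix", kind = "A22_INV",
                    matrix = inv, ids = animalIds(A22)))
}
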