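#' Accessors for singlestep classes
#'
#' Small generic accessors used across the package instead of direct slot
#' access: `animalIds()` returns the identifiers an object is indexed by,
#' `nAnimals()` its count, `relKind()`/`relMatrix()` the tag and matrix of a
#' [RelationshipMatrix-class], `dosages()`/`snpMap()`/`snpFreqs()`/`nSnp()`
#' the parts of a [GenotypeData-class], `ebv()`/`fixedSolutions()` the parts
#' of a [SolutionSet-class], and `snpWeights()`/`snpEffects()` the numeric
#' vectors inside [SnpWeights-class] and [SnpEffects-class].
#'
#' @param object an object of the documented classes.
#' @return The corresponding component; see each class page.
#' @name accessors
#' @aliases animalIds nAnimals relKind relMatrix dosages snpMap snpFreqs nSnp
#'   ebv fixedSolutions snpWeights snpEffects
NULL

#' @rdname accessors
#' @export
setGeneric("animalIds", function(object) standardGeneric("animalIds"))
#' @rdname accessors
#' @export
setGeneric("nAnimals", function(object) standardGeneric("nAnimals"))
#' @rdname accessors
#' @export
setGeneric("relKind", function(object) standardGeneric("relKind"))
#' @rdname accessors
#' @export
setGeneric("relMatrix", function(object) standardGeneric("relMatrix"))
#' @rdname accessors
#' @export
setGeneric("dosages", function(object) standardGeneric("dosages"))
#' @rdname accessors
#' @export
setGeneric("snpMap", function(object) standardGeneric("snpMap"))
#' @rdname accessors
#' @export
setGeneric("snpFreqs", function(object) standardGeneric("snpFreqs"))
#' @rdname accessors
#' @export
setGeneric("nSnp", function(object) standardGeneric("nSnp"))
#' @rdname accessors
#' @export
setGeneric("ebv", function(object) standardGeneric("ebv"))
#' @rdname accessors
#' @export
setGeneric("fixedSolutions", function(object) standardGeneric("fixedSolutions"))
#' @rdname accessors
#' @export
setGeneric("snpWeights", function(object) standardGeneric("snpWeights"))
#' @rdname accessors
#' @export
setGeneric("snpEffects", function(object) standardGeneric("snpEffects"))

#' Inbreeding coefficients from a sorted pedigree
#'
#' @param ped a [Pedigree-class].
#' @param ... unused.
#' @return numeric vector of inbreeding coefficients F, named by animal id.
#' @export
setGeneric("inbreeding", function(ped, ...) standardGeneric("inbreeding"))

## ---- methods -------------------------------------------------------------

#' @rdname accessors
setMethod("animalIds", "Pedigree", function(object) object@id)
#' @rdname accessors
setMethod("animalIds", "GenotypeData", function(object) object@ids)
#' @rdname accessors
setMethod("animalIds", "RelationshipMatrix", function(object) object@ids)
#' @rdname accessors
setMethod("nAnimals", "Pedigree", function(object) length(object@id))
#' @rdname accessors
setMethod("nAnimals", "GenotypeData", function(object) length(object@ids))
#' @rdname accessors
setMethod("relKind", "RelationshipMatrix", function(object) object@kind)
#' @rdname accessors
setMethod("relMatrix", "RelationshipMatrix", function(object) object@matrix)
#' @rdname accessors
setMethod("dosages", "GenotypeData", function(object) object@dosage)
#' @rdname accessors
setMethod("snpMap", "GenotypeData", function(object) object@map)
#' @rdname accessors
setMethod("snpFreqs", "GenotypeData", function(object) object@freqs)
#' @rdname accessors
setMethod("nSnp", "GenotypeData", function(object) ncol(object@dosage))
#' @rdname accessors
setMethod("ebv", "SolutionSet", function(object) object@ebv)
#' @rdname accessors
setMethod("fixedSolutions", "SolutionSet", function(object) object@fixed)
#' @rdname accessors
setMethod("snpWeights", "SnpWeights", function(object) object@d)
#' @rdname accessors
setMethod("snpEffects", "SnpEffects", function(object) object@u)

setMethod("show", "Pedigree", function(object) {
  n <- length(object@id)
  nf <- sum(is.na(object@sire) & is.na(object@dam))
  yr <- range(object@birthYear, na.rm = TRUE)
  cat(sprintf("Pedigree: %d animals (%d founders)", n, nf))
  if (all(is.finite(yr))) cat(sprintf(", birth years %d-%d", yr[1], yr[2]))
  cat("\n")
})

setMethod("show", "RelationshipMatrix", function(object) {
  cat(sprintf("RelationshipMatrix '%s': %d x %d (%s)\n", object@kind,
              nrow(object@matrix), ncol(object@matrix),
              if (is(object@matrix, "sparseMatrix")) "sparse" else "dense"))
})

setMethod("show", "GenotypeData", function(object) {
  cat(sprintf("GenotypeData: %d animals x %d SNPs on %d chromosome(s)\n",
              nrow(object@dosage), ncol(object@dosage),
              length(unique(object@map$chrom))))
  nmiss <- sum(is.na(object@dosage))
  if (nmiss > 0) cat(sprintf("  %d missing dosages (pre-QC)\n", nmiss))
})

setMethod("show", "SolutionSet", function(object) {
  cat(sprintf("SolutionSet [%s, %s]: %d EBVs, %d fixed-effect levels%s\n",
              object@modelTag, object@datasetTag, length(object@ebv),
              nrow(object@fixed),
              if (isTRUE(object@converged)) "" else " (NOT converged)"))
})

setMethod("show", "SnpWeights", function(object) {
  cat(sprintf(
    "SnpWeights: %d SNPs, iteration %d, CT = %s, limit = %s, trace = %.4f\n",
    length(object@d), object@iteration, format(object@CT),
    format(object@limit), sum(object@d)))
})

setMethod("show", "SnpEffects", function(object) {
  cat(sprintf("SnpEffects: %d SNPs, sd(u) = %.4g\n",
              length(object@u), object@sdU))
})

setMethod("show", "PosteriorSamples", function(object) {
  cat(sprintf(
    "PosteriorSamples: %d retained draws (%s) of chain %g (burn-in %g, thin %g)\n",
    nrow(object@draws), paste(colnames(object@draws), collapse = ", "),
    object@chain, object@burnIn, object@thin))
})
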