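## Plain-text readers/writers for the dialects the package consumes.

#' Write a pedigree CSV
#'
#' Columns `animal,sire,dam,birth_year,sex`; unknown parents written as the
#' `unknown` token. Round-trips through [readPedigree()].
#'
#' @param ped a [Pedigree-class].
#' @param path output file.
#' @param unknown token for unknown parents (default `"0"`).
#' @return invisibly, `path`.
#' @export
writePedigree <- function(ped, path, unknown = "0") {
  df <- data.frame(
    animal = ped@id,
    sire = ifelse(is.na(ped@sire), unknown, ped@id[ped@sire]),
    dam = ifelse(is.na(ped@dam), unknown, ped@id[ped@dam]),
    birth_year = ped@birthYear,
    sex = ped@sex)
  utils::write.table(df, path, quote = FALSE, row.names = FALSE, sep = ",")
  invisible(path)
}

#' Read a phenotype CSV
#'
#' Expects a header with `animal`, one column per trait, and the
#' fixed-effect columns (`contemporary_group`, `parity_class`,
#' `birth_year` by default).
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
readPhenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, strip.white = TRUE)
  if (!"animal" %in% names(df)) stop("phenotype file lacks 'animal' column")
  df$animal <- as.character(df$animal)
  df
}

#' Write a phenotype CSV
#'
#' @param phenotypes data.frame as produced by [simulatePhenotypes()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writePhenotypes <- function(phenotypes, path) {
  utils::write.table(phenotypes, path, quote = FALSE, row.names = FALSE,
                     sep = ",")
  invisible(path)
}

#' Write a SolutionSet as TSV
#'
#' Two sections in one file-pair: `<stem>_fixed.tsv` (effect, level,
#' estimate) and `<stem>_ebv.tsv` (animal, ebv).
#'
#' @param sol a [SolutionSet-class].
#' @param stem output path stem.
#' @return invisibly, the two paths.
#' @export
writeSolutions <- function(sol, stem) {
  pf <- paste0(stem, "_fixed.tsv")
  pe <- paste0(stem, "_ebv.tsv")
  utils::write.table(fixedSolutions(sol), pf, quote = FALSE,
                     row.names = FALSE, sep = "\t")
  utils::write.table(data.frame(animal = names(ebv(sol)), ebv = ebv(sol)),
                     pe, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(c(pf, pe))
}
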