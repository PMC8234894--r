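## Genotype container, readers, and quality control.

#' Construct a GenotypeData object
#'
#' Stores an animals-by-SNP additive dosage matrix with its SNP map. Columns
#' are reordered so the map is sorted by (chromosome, position); the per-SNP
#' allele frequency of the counted allele, `p_i = mean(dosage_i)/2`, is
#' computed from the stored ("current") animals, ignoring missing values.
#'
#' @param dosage numeric matrix of 0/1/2 dosages (NA = missing), rows =
#'   animals, columns = SNPs.
#' @param map data.frame with columns `snp_id`, `chrom`, `pos` (one row per
#'   SNP column). If `NULL`, a single-chromosome map with unit spacing is
#'   generated.
#' @param ids animal ids; defaults to `rownames(dosage)`.
#' @return A [GenotypeData-class].
#' @export
GenotypeData <- function(dosage, map = NULL, ids = rownames(dosage)) {
  dosage <- as.matrix(dosage)
  if (is.null(ids)) stop("animal ids required (rownames or `ids`)")
  if (is.null(map)) {
    map <- data.frame(
      snp_id = if (is.null(colnames(dosage)))
        sprintf("snp%05d", seq_len(ncol(dosage))) else colnames(dosage),
      chrom = 1L, pos = seq_len(ncol(dosage)))
  }
  o <- order(map$chrom, map$pos)
  map <- map[o, , drop = FALSE]
  rownames(map) <- NULL
  dosage <- dosage[, o, drop = FALSE]
  colnames(dosage) <- map$snp_id
  rownames(dosage) <- ids
  new("GenotypeData", dosage = dosage, ids = as.character(ids),
      map = map, freqs = .colFreqs(dosage))
}

.colFreqs <- function(dosage) {
  p <- colMeans(dosage, na.rm = TRUE) / 2
  names(p) <- colnames(dosage)
  p
}

#' Current allele frequencies of a genotype set
#'
#' `p_i = mean(column i, ignoring missing)/2`: the frequency of the counted
#' allele in the supplied ("current") genotyped animals, the centering used
#' by the VanRaden matrix.
#'
#' @param g a [GenotypeData-class].
#' @return named numeric vector of per-SNP frequencies.
#' @export
alleleFrequencies <- function(g) {
  if (nSnp(g) == 0 || nAnimals(g) == 0) stop("empty genotype matrix")
  allNA <- colSums(!is.na(dosages(g))) == 0
  if (any(allNA)) {
    stop("SNP(s) with all dosages missing: ",
         paste(utils::head(snpMap(g)$snp_id[allNA], 5), collapse = ", "))
  }
  .colFreqs(dosages(g))
}

#' Genotype quality control
#'
#' Applies, in this order: SNP call rate, minor allele frequency, deviation
#' from Hardy-Weinberg heterozygosity, then animal call rate; any dosage
#' still missing afterwards is replaced by its column mean (2p). The HWE rule
#' removes SNPs with `|observed heterozygote frequency - 2p(1-p)|` above the
#' threshold, the convention of the preGSf90-style toolchains.
#'
#' @param g a [GenotypeData-class].
#' @param mafMin minimum minor allele frequency (default 0.05).
#' @param snpCallRate minimum per-SNP call rate (default 0.90).
#' @param hweMaxDev maximum absolute heterozygosity deviation (default 0.15).
#' @param animalCallRate minimum per-animal call rate (default 0.90).
#' @return list with `genotypes` (filtered, imputed [GenotypeData-class]) and
#'   `report` (data.frame of removal counts per rule).
#' @export
qcFilter <- function(g, mafMin = 0.05, snpCallRate = 0.90,
                     hweMaxDev = 0.15, animalCallRate = 0.90) {
  stopifnot(mafMin >= 0, mafMin <= 1, snpCallRate >= 0, snpCallRate <= 1,
            hweMaxDev >= 0, hweMaxDev <= 1,
            animalCallRate >= 0, animalCallRate <= 1)
  X <- dosages(g)
  keepSnp <- rep(TRUE, ncol(X))

  cr <- colMeans(!is.na(X))
  dropCR <- cr < snpCallRate
  keepSnp[dropCR] <- FALSE

  p <- colMeans(X, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  dropMAF <- keepSnp & (is.na(maf) | maf < mafMin)
  keepSnp[dropMAF] <- FALSE

  het <- colMeans(X == 1, na.rm = TRUE)
  hweDev <- abs(het - 2 * p * (1 - p))
  dropHWE <- keepSnp & !is.na(hweDev) & hweDev > hweMaxDev
  keepSnp[dropHWE] <- FALSE

  if (!any(keepSnp)) stop("all SNPs removed by QC")
  X2 <- X[, keepSnp, drop = FALSE]

  acr <- rowMeans(!is.na(X2))
  keepAnimal <- acr >= animalCallRate
  if (!any(keepAnimal)) stop("all animals removed by QC")
  X2 <- X2[keepAnimal, , drop = FALSE]

  ## mean-impute what is left (2p of the retained animals)
  miss <- which(is.na(X2), arr.ind = TRUE)
  if (nrow(miss)) {
    cm <- colMeans(X2, na.rm = TRUE)
    X2[miss] <- cm[miss[, "col"]]
  }

  report <- data.frame(
    rule = c("snp_call_rate", "maf", "hwe_deviation", "animal_call_rate"),
    removed = c(sum(dropCR), sum(dropMAF), sum(dropHWE), sum(!keepAnimal)),
    threshold = c(snpCallRate, mafMin, hweMaxDev, animalCallRate))
  out <- GenotypeData(X2, map = snpMap(g)[keepSnp, , drop = FALSE],
                      ids = animalIds(g)[keepAnimal])
  list(genotypes = out, report = report)
}

#' Read genotypes from PLINK .raw or CSV
#'
#' `format = "raw"` expects the PLINK additive-dosage export (`--recode A`):
#' whitespace-separated with header `FID IID PAT MAT SEX PHENOTYPE` followed
#' by one `<snp>_<allele>` column per SNP. `format = "csv"` expects a header
#' row of SNP ids and a first column of animal ids. An optional SNP map TSV
#' (`snp_id`, `chrom`, `pos`) supplies genomic coordinates.
#'
#' @param path genotype file.
#' @param format `"raw"` or `"csv"`.
#' @param mapPath optional SNP map TSV with a header.
#' @return A [GenotypeData-class].
#' @examples
#' g <- readGenotypes(system.file("extdata", "example_genotypes.raw",
#'                                package = "singlestep"),
#'                    mapPath = system.file("extdata",
#'                                          "example_snp_map.tsv",
#'                                          package = "singlestep"))
#' g
#' alleleFrequencies(g)
#' @export
readGenotypes <- function(path, format = c("raw", "csv"), mapPath = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  if (format == "raw") {
    df <- utils::read.table(path, header = TRUE, check.names = FALSE)
    meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (!all(meta %in% names(df))) {
      stop("not a PLINK .raw file (missing ",
           paste(setdiff(meta, names(df)), collapse = ", "), ")")
    }
    ids <- as.character(df$IID)
    X <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
    colnames(X) <- sub("_[ACGT0-9]+$", "", colnames(X))
  } else {
    df <- utils::read.csv(path, check.names = FALSE)
    ids <- as.character(df[[1]])
    X <- as.matrix(df[, -1, drop = FALSE])
  }
  storage.mode(X) <- "double"
  map <- NULL
  if (!is.null(mapPath)) {
    map <- utils::read.table(mapPath, header = TRUE, sep = "\t")
    map <- map[match(colnames(X), map$snp_id), , drop = FALSE]
    if (anyNA(map$snp_id)) stop("SNP map does not cover all genotyped SNPs")
  }
  GenotypeData(X, map = map, ids = ids)
}

#' Write genotypes in the dialects the readers consume
#'
#' @param g a [GenotypeData-class].
#' @param path output file.
#' @param format `"raw"` (PLINK additive export) or `"csv"`.
#' @param mapPath optional path for the SNP map TSV.
#' @return invisibly, `path`.
#' @export
writeGenotypes <- function(g, path, format = c("raw", "csv"),
                           mapPath = NULL) {
  format <- match.arg(format)
  X <- dosages(g)
  if (format == "raw") {
    df <- data.frame(FID = animalIds(g), IID = animalIds(g), PAT = 0,
                     MAT = 0, SEX = 0, PHENOTYPE = -9, check.names = FALSE)
    snps <- as.data.frame(X)
    names(snps) <- paste0(snpMap(g)$snp_id, "_A")
    utils::write.table(cbind(df, snps), path, quote = FALSE,
                       row.names = FALSE, sep = " ")
  } else {
    df <- data.frame(animal = animalIds(g), X, check.names = FALSE)
    utils::write.table(df, path, quote = FALSE, row.names = FALSE, sep = ",")
  }
  if (!is.null(mapPath)) {
    utils::write.table(snpMap(g), mapPath, quote = FALSE,
                       row.names = FALSE, sep = "\t")
  }
  invisible(path)
}
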