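#' Construct a GenotypeMatrix
#'
#' Sorts the map by (chromosome, position), reorders dosage columns to
#' match, and computes per-SNP reference-allele frequencies from the
#' non-missing dosages unless `alleleFreq` is supplied (e.g. base-population
#' frequencies). SNPs with every dosage missing get frequency `NaN` and are
#' flagged with a warning.
#'
#' @param dosage numeric matrix (animals x SNPs) of 0/1/2 dosages, `NA`
#'   missing; rownames = animal ids, colnames = SNP ids.
#' @param map data.frame with columns `snp`, `chrom`, `pos`.
#' @param alleleFreq optional numeric vector of frequencies in map order
#'   (after sorting).
#' @return a [GenotypeMatrix-class].
#' @export
GenotypeMatrix <- function(dosage, map, alleleFreq = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (!all(c("snp", "chrom", "pos") %in% names(map)))
    stop("map must have columns snp, chrom, pos")
  if (nrow(map) != ncol(dosage))
    stop("map rows (", nrow(map), ") do not match dosage columns (",
         ncol(dosage), ")")
  if (is.null(colnames(dosage))) colnames(dosage) <- map$snp
  if (!identical(as.character(colnames(dosage)), as.character(map$snp)))
    stop("dosage column names do not match map SNP ids")
  bad <- dosage[!is.na(dosage) & !(dosage %in% c(0, 1, 2))]
  if (length(bad))
    stop("invalid dosage code(s): ", paste(unique(bad), collapse = ", "))
  ord <- order(chromRank(map$chrom), map$pos)
  map <- map[ord, , drop = FALSE]
  rownames(map) <- NULL
  map$chrom <- as.character(map$chrom)
  dosage <- dosage[, ord, drop = FALSE]
  if (is.null(alleleFreq)) {
    alleleFreq <- colMeans(dosage, na.rm = TRUE) / 2
  } else {
    alleleFreq <- alleleFreq[ord]
  }
  if (anyNA(alleleFreq) || any(is.nan(alleleFreq)))
    warning("SNP(s) with all dosages missing: allele frequency undefined")
  new("GenotypeMatrix", dosage = dosage, map = map,
      alleleFreq = unname(alleleFreq))
}

#' Read genotype and map files
#'
#' The genotype TSV holds one row per animal: an `animal` column followed by
#' one dosage column per SNP (missing coded `NA` or `5`, the BLUPF90
#' convention). The map TSV has columns `snp`, `chrom`, `pos`.
#'
#' @param genoPath,mapPath file paths.
#' @return a [GenotypeMatrix-class] with the map sorted by (chrom, pos) and
#'   allele frequencies computed from the data.
#' @export
readGenotypes <- function(genoPath, mapPath) {
  geno <- readTsv(genoPath)
  map <- readTsv(mapPath)
  if (!"animal" %in% names(geno))
    stop("genotype file must have an 'animal' column")
  ids <- as.character(geno$animal)
  dosage <- as.matrix(geno[, setdiff(names(geno), "animal"), drop = FALSE])
  storage.mode(dosage) <- "double"
  dosage[dosage == 5] <- NA_real_
  rownames(dosage) <- ids
  if (!setequal(colnames(dosage), map$snp))
    stop("genotype columns and map SNP ids disagree")
  dosage <- dosage[, as.character(map$snp), drop = FALSE]
  GenotypeMatrix(dosage, map)
}

#' Write genotype and map files
#'
#' Inverse of [readGenotypes()]; missing dosages are written as `NA`.
#'
#' @param geno a [GenotypeMatrix-class].
#' @param genoPath,mapPath output paths.
#' @export
writeGenotypes <- function(geno, genoPath, mapPath) {
  df <- data.frame(animal = rownames(geno@dosage), geno@dosage,
                   check.names = FALSE, stringsAsFactors = FALSE)
  writeTsv(df, genoPath)
  writeTsv(geno@map, mapPath)
  invisible(c(genoPath, mapPath))
}

#' Read or write a phenotype table
#'
#' Phenotype tables are TSVs with columns `animal`, `trait`, `cg`, `age`
#' (age in days).
#'
#' @param path file path.
#' @return `readPhenotypes`: a data.frame with those four columns.
#' @export
readPhenotypes <- function(path) {
  df <- readTsv(path, colClasses = c(animal = "character", cg = "character"))
  need <- c("animal", "trait", "cg", "age")
  if (!all(need %in% names(df)))
    stop("phenotype file must have columns ", paste(need, collapse = ", "))
  if (any(df$age < 0)) stop("negative age")
  df[, need]
}

#' @rdname readPhenotypes
#' @param pheno data.frame as returned by [readPhenotypes()].
#' @export
writePhenotypes <- function(pheno, path) {
  writeTsv(pheno, path)
}
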