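#' @importClassesFrom Matrix Matrix
NULL

#' @rdname accessors
#' @export
setGeneric("nAnimals", function(x) standardGeneric("nAnimals"))
#' @rdname accessors
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))
#' @rdname accessors
#' @export
setGeneric("dosageMatrix", function(x) standardGeneric("dosageMatrix"))
#' @rdname accessors
#' @export
setGeneric("snpMap", function(x) standardGeneric("snpMap"))
#' @rdname accessors
#' @export
setGeneric("alleleFreq", function(x) standardGeneric("alleleFreq"))
#' @rdname accessors
#' @export
setGeneric("snpRanges", function(x) standardGeneric("snpRanges"))
#' @rdname accessors
#' @export
setGeneric("pedIds", function(x) standardGeneric("pedIds"))
#' @rdname accessors
#' @export
setGeneric("sigmaA2", function(x) standardGeneric("sigmaA2"))
#' @rdname accessors
#' @export
setGeneric("sigmaE2", function(x) standardGeneric("sigmaE2"))
#' @rdname accessors
#' @export
setGeneric("h2", function(x) standardGeneric("h2"))
#' @rdname accessors
#' @export
setGeneric("gebv", function(x) standardGeneric("gebv"))
#' @rdname accessors
#' @export
setGeneric("fixedEffects", function(x) standardGeneric("fixedEffects"))
#' @rdname accessors
#' @export
setGeneric("snpEffects", function(x) standardGeneric("snpEffects"))
#' @rdname accessors
#' @export
setGeneric("snpVariances", function(x) standardGeneric("snpVariances"))
#' @rdname accessors
#' @export
setGeneric("snpWeights", function(x) standardGeneric("snpWeights"))
#' @rdname accessors
#' @export
setGeneric("iterationStates", function(x) standardGeneric("iterationStates"))

#' Accessors for wssgblup classes
#'
#' Small accessor generics exposing slots of the package's S4 classes:
#' dimensions, dosages, SNP map (also as a `GRanges` via `snpRanges`),
#' pedigree ids, variance components, breeding values and per-SNP GWAS
#' results.
#'
#' @param x an object of the documented classes.
#' @return The corresponding component; see each class page.
#' @name accessors
NULL

#' @rdname accessors
setMethod("nAnimals", "Pedigree", function(x) length(x@id))
#' @rdname accessors
setMethod("nAnimals", "GenotypeMatrix", function(x) nrow(x@dosage))
#' @rdname accessors
setMethod("nSnps", "GenotypeMatrix", function(x) ncol(x@dosage))
#' @rdname accessors
setMethod("dosageMatrix", "GenotypeMatrix", function(x) x@dosage)
#' @rdname accessors
setMethod("snpMap", "GenotypeMatrix", function(x) x@map)
#' @rdname accessors
setMethod("alleleFreq", "GenotypeMatrix", function(x) x@alleleFreq)
#' @rdname accessors
setMethod("pedIds", "Pedigree", function(x) x@id)
#' @rdname accessors
setMethod("sigmaA2", "VarianceComponents", function(x) x@sigmaA2)
#' @rdname accessors
setMethod("sigmaE2", "VarianceComponents", function(x) x@sigmaE2)
#' @rdname accessors
setMethod("h2", "VarianceComponents", function(x) x@h2)
#' @rdname accessors
setMethod("gebv", "MMESolution", function(x) x@gebv)
#' @rdname accessors
setMethod("gebv", "GwasRun", function(x) x@gebv)
#' @rdname accessors
setMethod("fixedEffects", "MMESolution", function(x) x@betaHat)
#' @rdname accessors
setMethod("snpEffects", "GwasRun", function(x) finalState(x)@uHat)
#' @rdname accessors
setMethod("snpVariances", "GwasRun", function(x) finalState(x)@snpVar)
#' @rdname accessors
setMethod("snpWeights", "GwasRun", function(x) finalState(x)@d)
#' @rdname accessors
setMethod("iterationStates", "GwasRun", function(x) x@states)

#' @rdname accessors
setMethod("snpRanges", "GenotypeMatrix", function(x) {
  GenomicRanges::GRanges(
    seqnames = as.character(x@map$chrom),
    ranges = IRanges::IRanges(start = x@map$pos, width = 1L),
    snp = x@map$snp)
})

#' Final iteration state of a GWAS run
#'
#' @param x a [GwasRun-class].
#' @return the last [SNPWeightState-class].
#' @export
finalState <- function(x) {
  stopifnot(is(x, "GwasRun"))
  x@states[[length(x@states)]]
}

setMethod("show", "Pedigree", function(object) {
  n <- length(object@id)
  nf <- sum(object@sire == 0L & object@dam == 0L)
  cat("Pedigree with", n, "animals (", nf, "founders )\n")
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object@dosage), "animals x",
      ncol(object@dosage), "SNPs on",
      length(unique(object@map$chrom)), "chromosomes\n")
  miss <- mean(is.na(object@dosage))
  cat(sprintf("  missing dosages: %.2f%%\n", 100 * miss))
})

setMethod("show", "QCReport", function(object) {
  cat("QCReport:", object@before[1], "x", object@before[2], "->",
      object@after[1], "x", object@after[2], "\n")
  cat("  samples removed:\n")
  for (nm in names(object@samplesRemoved))
    cat(sprintf("    %-22s %d\n", nm, object@samplesRemoved[[nm]]))
  cat("  SNPs removed:\n")
  for (nm in names(object@snpsRemoved))
    cat(sprintf("    %-22s %d\n", nm, object@snpsRemoved[[nm]]))
})

setMethod("show", "VarianceComponents", function(object) {
  cat(sprintf(
    "VarianceComponents: sigmaA2 = %.4g, sigmaE2 = %.4g, h2 = %.3f",
    object@sigmaA2, object@sigmaE2, object@h2))
  if (!is.na(object@seH2)) cat(sprintf(" +/- %.3f", object@seH2))
  cat(sprintf("\n  %d iterations, converged: %s, logLik = %.4f\n",
              object@nIterations, object@converged, object@loglik))
})

setMethod("show", "MMESolution", function(object) {
  cat(sprintf(
    "MMESolution (%s): %d fixed effects, %d breeding values, lambda = %.4g\n",
    object@solver, length(object@betaHat), length(object@gebv),
    object@lambda))
})

setMethod("show", "GwasRun", function(object) {
  st <- finalState(object)
  cat(sprintf("GwasRun %s: %d iterations over %d SNPs, converged: %s\n",
              object@method, length(object@states), length(st@uHat),
              st@converged))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: %d founders, %d generations, %d chr x %d SNPs, h2 = %.2f (seed %d)\n",
    object@nFounders, object@nGenerations, object@nChromosomes,
    object@nSnpsPerChromosome, object@traitH2, object@seed))
})

setMethod("show", "SimulatedDataset", function(object) {
  cat("SimulatedDataset:\n  ")
  show(object@pedigree)
  if (!is.null(object@genotypes)) {
    cat("  ")
    show(object@genotypes)
  }
  cat("  phenotypes:", nrow(object@phenotypes), "records\n")
})

setMethod("show", "RelationshipSet", function(object) {
  cat("RelationshipSet:", nrow(object@A), "pedigree animals,",
      length(object@genotypedIndex), "genotyped\n")
})
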