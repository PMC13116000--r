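#' @import methods
#' @importFrom stats var sd setNames rnorm rbinom runif rpois p.adjust phyper
#'   optimize complete.cases
#' @importFrom utils read.table write.table head
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Pedigree of a breeding population
#'
#' An ordered pedigree: every animal appears once, parents precede their
#' offspring, and unknown parents are coded 0. Construct with
#' [Pedigree()] or [readPedigree()]; both topologically sort the input and
#' reject cycles and duplicate ids.
#'
#' @slot id character vector of animal ids, in (sorted) pedigree order.
#' @slot sire,dam integer positions of each animal's parents in `id`
#'   (0 = unknown). Always strictly less than the animal's own position.
#'
#' @seealso [numeratorRelationship()], [aInverse()], [inbreeding()]
#' @export
setClass("Pedigree",
  representation(id = "character", sire = "integer", dam = "integer"))

setValidity("Pedigree", function(object) {
  n <- length(object@id)
  if (length(object@sire) != n || length(object@dam) != n)
    return("id, sire and dam must have equal length")
  if (anyDuplicated(object@id))
    return(paste("duplicated animal id:", object@id[duplicated(object@id)][1]))
  idx <- seq_len(n)
  if (n && (any(object@sire >= idx) || any(object@dam >= idx)))
    return("parents must precede offspring (pedigree not topologically ordered)")
  if (n && (any(object@sire < 0L) || any(object@dam < 0L)))
    return("parent indices must be >= 0")
  TRUE
})

#' SNP dosage matrix with map and allele frequencies
#'
#' Dosages are counts of the reference allele (0/1/2, `NA` = missing), one
#' row per animal and one column per SNP. The map is kept sorted by
#' (chromosome, position); dosage columns follow map order. Allele
#' frequencies are computed from non-missing dosages unless supplied.
#'
#' @slot dosage numeric matrix, animals x SNPs, values in {0,1,2,NA}.
#' @slot map data.frame with columns `snp`, `chrom`, `pos` (1-based bp),
#'   sorted by chromosome then position.
#' @slot alleleFreq numeric vector of per-SNP reference-allele frequencies
#'   (`NaN` where every dosage is missing).
#'
#' @seealso [readGenotypes()], [qcFilter()], [vanRadenG()]
#' @export
setClass("GenotypeMatrix",
  representation(dosage = "matrix", map = "data.frame",
                 alleleFreq = "numeric"))

setValidity("GenotypeMatrix", function(object) {
  d <- object@dosage
  if (ncol(d) != nrow(object@map))
    return("map rows must match dosage columns")
  if (length(object@alleleFreq) != ncol(d))
    return("alleleFreq length must match dosage columns")
  if (!all(c("snp", "chrom", "pos") %in% names(object@map)))
    return("map must have columns snp, chrom, pos")
  v <- d[!is.na(d)]
  if (length(v) && !all(v %in% c(0, 1, 2)))
    return("dosages must be 0, 1, 2 or NA")
  ord <- order(chromRank(object@map$chrom), object@map$pos)
  if (!identical(ord, seq_len(nrow(object@map))))
    return("map must be sorted by (chrom, pos)")
  TRUE
})

#' Genotype quality-control report
#'
#' Bookkeeping of [qcFilter()]: counts removed per rule and the matrix
#' dimensions before and after, satisfying before - sum(removed) = after on
#' each axis.
#'
#' @slot samplesRemoved,snpsRemoved named integer vectors of counts removed
#'   per rule, in order of application.
#' @slot before,after integer length-2 (animals, SNPs) dimensions.
#' @export
setClass("QCReport",
  representation(samplesRemoved = "integer", snpsRemoved = "integer",
                 before = "integer", after = "integer"))

setValidity("QCReport", function(object) {
  ok_s <- object@before[1] - sum(object@samplesRemoved) == object@after[1]
  ok_m <- object@before[2] - sum(object@snpsRemoved) == object@after[2]
  if (!ok_s) return("sample bookkeeping identity violated")
  if (!ok_m) return("SNP bookkeeping identity violated")
  TRUE
})

#' REML variance components for the animal model
#'
#' Result of [remlEstimate()]: additive genetic and residual variances, the
#' heritability they imply, its approximate standard error from the inverse
#' average-information matrix, and the iteration trace.
#'
#' @slot sigmaA2,sigmaE2 additive genetic and residual variance (trait
#'   units squared).
#' @slot h2 heritability sigmaA2 / (sigmaA2 + sigmaE2).
#' @slot seH2 delta-method standard error of h2 (`NA` if unavailable).
#' @slot nIterations number of REML iterations performed.
#' @slot converged logical convergence flag.
#' @slot loglik restricted log-likelihood at the final estimates.
#' @slot trace data.frame with one row per iteration.
#' @export
setClass("VarianceComponents",
  representation(sigmaA2 = "numeric", sigmaE2 = "numeric", h2 = "numeric",
                 seH2 = "numeric", nIterations = "integer",
                 converged = "logical", loglik = "numeric",
                 trace = "data.frame"))

setValidity("VarianceComponents", function(object) {
  if (object@sigmaA2 < 0) return("sigmaA2 must be >= 0")
  if (object@sigmaE2 <= 0) return("sigmaE2 must be > 0")
  h <- object@sigmaA2 / (object@sigmaA2 + object@sigmaE2)
  if (abs(h - object@h2) > 1e-12) return("h2 inconsistent with components")
  TRUE
})

#' Mixed-model equation solution
#'
#' Fixed-effect solutions and genomic/pedigree breeding values from
#' [solveMME()]. GEBVs are reported for every pedigree animal, phenotyped
#' or not.
#'
#' @slot betaHat named fixed-effect solutions (CG levels + age slope).
#' @slot gebv named breeding values, one per pedigree animal (trait units).
#' @slot lambda variance ratio sigmaE2 / sigmaA2 used in the equations.
#' @slot solver character, currently `"direct"` (sparse Cholesky).
#' @slot residualNorm relative residual of the normal equations.
#' @export
setClass("MMESolution",
  representation(betaHat = "numeric", gebv = "numeric", lambda = "numeric",
                 solver = "character", residualNorm = "numeric"))

setValidity("MMESolution", function(object) {
  if (object@lambda <= 0) return("lambda must be > 0")
  TRUE
})

#' State of one SNP-weighting iteration
#'
#' Per-SNP effects, variances and weights after one round of back-solving.
#' The weight vector `d` always satisfies the constant-variance constraint
#' sum(2pq * d) = sum(2pq).
#'
#' @slot method one of `"UM"`, `"QM"`, `"NLA"`.
#' @slot k non-linear A constant (`NA` for UM/QM).
#' @slot iteration iteration number (1-based).
#' @slot uHat per-SNP allele-substitution effects (trait units / allele).
#' @slot snpVar per-SNP variances uHat^2 * 2 p q.
#' @slot d per-SNP weights entering the weighted genomic relationship matrix.
#' @slot sdU standard deviation of `uHat`.
#' @slot converged logical.
#' @export
setClass("SNPWeightState",
  representation(method = "character", k = "numeric", iteration = "integer",
                 uHat = "numeric", snpVar = "numeric", d = "numeric",
                 sdU = "numeric", converged = "logical"))

setValidity("SNPWeightState", function(object) {
  m <- length(object@uHat)
  if (length(object@snpVar) != m || length(object@d) != m)
    return("uHat, snpVar and d must have equal length")
  if (m && any(object@d <= 0)) return("weights d must be > 0")
  TRUE
})

#' A complete weighted-GWAS run
#'
#' One analytical approach (UM, QM, or non-linear A at a given k): the
#' per-iteration [SNPWeightState-class] history, the final state, and the
#' variance components held fixed throughout.
#'
#' @slot method method label, e.g. `"UM"`, `"QM"`, `"A_1.125"`.
#' @slot k non-linear A constant (`NA` otherwise).
#' @slot states list of [SNPWeightState-class], one per iteration.
#' @slot varcomp the [VarianceComponents-class] used.
#' @slot gebv final-iteration breeding values of genotyped animals.
#' @export
setClass("GwasRun",
  representation(method = "character", k = "numeric", states = "list",
                 varcomp = "VarianceComponents", gebv = "numeric"))

setValidity("GwasRun", function(object) {
  if (!length(object@states)) return("at least one iteration required")
  if (!all(vapply(object@states, is, TRUE, "SNPWeightState")))
    return("states must be SNPWeightState objects")
  TRUE
})

#' Configuration of the gene-drop simulator
#'
#' Defaults describe a desk-scale population with the structure the analysis
#' assumes: discrete generations from a founder cohort, a 30-chromosome
#' genome with evenly spaced SNPs, a moderately heritable trait (h2 = 0.26)
#' controlled by explicit QTL plus a pedigree polygene, contemporary-group
#' fixed effects, a linear age covariate, and a genotyped subset of roughly
#' half the phenotyped animals.
#'
#' @slot nFounders,nGenerations,offspringPerMating population structure.
#' @slot nChromosomes,chromosomeLengthMorgans,nSnpsPerChromosome genome map.
#' @slot founderMafRange length-2 numeric in (0, 0.5].
#' @slot nQtl,traitH2,qtlVarianceFraction genetic architecture; the QTL
#'   fraction splits additive variance between explicit QTL and the
#'   pedigree polygene.
#' @slot nCg,cgEffectSd,ageRangeDays,ageSlope fixed-effect structure.
#' @slot genotypedFraction,missingGenotypeRate genotyping scheme.
#' @slot seed integer; fully determines the output.
#' @seealso [simulationConfig()], [simulateDataset()]
#' @export
setClass("SimulationConfig",
  representation(nFounders = "integer", nGenerations = "integer",
                 offspringPerMating = "integer", nChromosomes = "integer",
                 chromosomeLengthMorgans = "numeric",
                 nSnpsPerChromosome = "integer",
                 founderMafRange = "numeric", nQtl = "integer",
                 traitH2 = "numeric", qtlVarianceFraction = "numeric",
                 nCg = "integer", cgEffectSd = "numeric",
                 ageRangeDays = "integer", ageSlope = "numeric",
                 genotypedFraction = "numeric",
                 missingGenotypeRate = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  cnt <- c(object@nFounders, object@nChromosomes, object@nSnpsPerChromosome,
           object@offspringPerMating, object@nCg)
  if (any(cnt < 1L)) return("counts must be >= 1")
  if (object@nGenerations < 0L) return("nGenerations must be >= 0")
  if (object@nQtl < 0L) return("nQtl must be >= 0")
  if (object@traitH2 < 0 || object@traitH2 >= 1)
    return("traitH2 must be in [0, 1)")
  r <- object@founderMafRange
  if (length(r) != 2 || r[1] <= 0 || r[2] > 0.5 || r[1] > r[2])
    return("founderMafRange must be within (0, 0.5]")
  if (object@qtlVarianceFraction < 0 || object@qtlVarianceFraction > 1)
    return("qtlVarianceFraction must be in [0, 1]")
  if (object@genotypedFraction <= 0 || object@genotypedFraction > 1)
    return("genotypedFraction must be in (0, 1]")
  if (object@missingGenotypeRate < 0 || object@missingGenotypeRate >= 1)
    return("missingGenotypeRate must be in [0, 1)")
  if (length(object@ageRangeDays) != 2 ||
      object@ageRangeDays[1] > object@ageRangeDays[2] ||
      object@ageRangeDays[1] < 0)
    return("ageRangeDays must be a non-decreasing pair of non-negative ints")
  TRUE
})

#' A simulated dataset with known truth
#'
#' @slot pedigree a [Pedigree-class].
#' @slot genotypes a [GenotypeMatrix-class] of the genotyped subset, or
#'   `NULL` when `qtlVarianceFraction = 0` simulations skip genotyping.
#' @slot phenotypes data.frame (animal, trait, cg, age).
#' @slot truth list: `tbv` (named, all animals), `qtlSnp`, `qtlEffect`,
#'   `sigmaA2True`, `sigmaE2True`.
#' @export
setClass("SimulatedDataset",
  representation(pedigree = "Pedigree", genotypes = "ANY",
                 phenotypes = "data.frame", truth = "list"))

setValidity("SimulatedDataset", function(object) {
  if (!is.null(object@genotypes) && !is(object@genotypes, "GenotypeMatrix"))
    return("genotypes must be NULL or a GenotypeMatrix")
  ids <- object@pedigree@id
  if (!all(object@phenotypes$animal %in% ids))
    return("phenotyped animal missing from pedigree")
  if (!is.null(object@genotypes) &&
      !all(rownames(object@genotypes@dosage) %in% ids))
    return("genotyped animal missing from pedigree")
  TRUE
})

#' Pedigree, genomic and unified relationship matrices
#'
#' Container built by [buildRelationships()]: the numerator relationship
#' matrix A and its sparse inverse, the genotyped block A22, the (blended)
#' genomic relationship matrix, and the inverse of the unified matrix H.
#'
#' @slot A dense numerator relationship matrix in pedigree order.
#' @slot Ainv sparse inverse of A.
#' @slot A22 dense pedigree relationships among genotyped animals.
#' @slot Graw,Gblend raw and blended genomic relationship matrices.
#' @slot Hinv sparse inverse of the unified relationship matrix.
#' @slot genotypedIndex positions of genotyped animals in pedigree order.
#' @export
setClass("RelationshipSet",
  representation(A = "matrix", Ainv = "Matrix", A22 = "matrixOrNULL",
                 Graw = "matrixOrNULL", Gblend = "matrixOrNULL",
                 Hinv = "Matrix", genotypedIndex = "integer"))
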