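#' Genotype quality control
#'
#' Applies the panel QC rules in a fixed order: (1) samples by call rate,
#' (2) SNPs by call rate, (3) monomorphic SNPs, (4) SNPs by minor allele
#' frequency, (5) Mendelian conflicts — samples whose opposing-homozygote
#' conflict rate across compared SNPs exceeds `mendelSampleRate` are dropped
#' first, then any SNP showing at least one remaining parent-offspring
#' conflict is removed. Allele frequencies are recomputed from the retained
#' animals before the MAF rule and again at the end.
#'
#' A parent-offspring conflict is an opposing-homozygote pair (dosages 0 and
#' 2) at a SNP where both animals are genotyped.
#'
#' @param geno a [GenotypeMatrix-class].
#' @param ped a [Pedigree-class] supplying parent-offspring pairs; `NULL`
#'   skips the Mendelian step.
#' @param sampleCallMin,snpCallMin minimum call rates (default 0.90).
#' @param mafMin minimum minor allele frequency (default 0.05).
#' @param mendelSampleRate maximum tolerated per-sample conflict rate
#'   (default 0.02).
#' @return list with elements `genotypes` (filtered [GenotypeMatrix-class])
#'   and `report` (a [QCReport-class]).
#' @examples
#' g <- GenotypeMatrix(
#'   matrix(c(0, 1, 2, 2, 2, 2), 3,
#'          dimnames = list(c("a", "b", "c"), c("s1", "s2"))),
#'   data.frame(snp = c("s1", "s2"), chrom = "1", pos = c(100L, 200L)))
#' qc <- qcFilter(g, ped = NULL, mafMin = 0.05)
#' qc$report  # s2 removed as monomorphic
#' @export
qcFilter <- function(geno, ped = NULL, sampleCallMin = 0.90,
                     snpCallMin = 0.90, mafMin = 0.05,
                     mendelSampleRate = 0.02) {
  stopifnot(is(geno, "GenotypeMatrix"))
  if (any(c(sampleCallMin, snpCallMin, mafMin) <= 0) ||
      any(c(sampleCallMin, snpCallMin) > 1))
    stop("thresholds must be in (0, 1]")
  d <- geno@dosage
  map <- geno@map
  before <- dim(d)
  sRem <- c(call_rate = 0L, mendelian = 0L)
  mRem <- c(call_rate = 0L, monomorphic = 0L, maf = 0L, mendelian = 0L)

  # 1. sample call rate
  cr <- rowMeans(!is.na(d))
  drop_s <- cr < sampleCallMin
  sRem["call_rate"] <- sum(drop_s)
  d <- d[!drop_s, , drop = FALSE]

  # 2. SNP call rate
  cr <- colMeans(!is.na(d))
  drop_m <- cr < snpCallMin
  mRem["call_rate"] <- sum(drop_m)
  d <- d[, !drop_m, drop = FALSE]
  map <- map[!drop_m, , drop = FALSE]

  # 3. monomorphic, 4. MAF (frequencies recomputed on retained samples)
  p <- colMeans(d, na.rm = TRUE) / 2
  drop_m <- !is.nan(p) & (p == 0 | p == 1)
  mRem["monomorphic"] <- sum(drop_m)
  d <- d[, !drop_m, drop = FALSE]
  map <- map[!drop_m, , drop = FALSE]
  p <- p[!drop_m]
  drop_m <- pmin(p, 1 - p) < mafMin
  mRem["maf"] <- sum(drop_m)
  d <- d[, !drop_m, drop = FALSE]
  map <- map[!drop_m, , drop = FALSE]

  # 5. Mendelian conflicts: samples above the conflict-rate cap, then SNPs
  if (!is.null(ped) && nrow(d) && ncol(d)) {
    cm <- mendelConflicts(d, ped)
    rate <- ifelse(cm$sampleCompared > 0,
                   cm$sampleConflicts / cm$sampleCompared, 0)
    drop_s <- rate > mendelSampleRate
    sRem["mendelian"] <- sum(drop_s)
    d <- d[!drop_s, , drop = FALSE]
    if (nrow(d)) {
      cm <- mendelConflicts(d, ped)
      drop_m <- cm$snpConflicts >= 1L
      mRem["mendelian"] <- sum(drop_m)
      d <- d[, !drop_m, drop = FALSE]
      map <- map[!drop_m, , drop = FALSE]
    }
  }

  if (ncol(d) == 0L) stop("empty panel: all SNPs removed by QC")
  if (nrow(d) == 0L) stop("all samples removed by QC")
  out <- GenotypeMatrix(d, map)
  report <- new("QCReport", samplesRemoved = sRem, snpsRemoved = mRem,
                before = as.integer(before), after = dim(out@dosage))
  list(genotypes = out, report = report)
}

# Opposing-homozygote counts per SNP and per sample over all genotyped
# parent-offspring pairs of `ped` present in the dosage rownames.
mendelConflicts <- function(d, ped) {
  ids <- rownames(d)
  pos <- match(ped@id, ids)  # pedigree order -> row, NA if not genotyped
  m <- ncol(d)
  snpConf <- integer(m)
  sampConf <- setNames(numeric(nrow(d)), ids)
  sampComp <- setNames(numeric(nrow(d)), ids)
  n <- length(ped@id)
  for (i in seq_len(n)) {
    ci <- pos[i]
    if (is.na(ci)) next
    for (par in c(ped@sire[i], ped@dam[i])) {
      if (par == 0L) next
      pi <- pos[par]
      if (is.na(pi)) next
      a <- d[ci, ]
      b <- d[pi, ]
      both <- !is.na(a) & !is.na(b)
      conf <- both & abs(a - b) == 2
      snpConf <- snpConf + conf
      nb <- sum(both)
      nc <- sum(conf)
      sampConf[ci] <- sampConf[ci] + nc
      sampConf[pi] <- sampConf[pi] + nc
      sampComp[ci] <- sampComp[ci] + nb
      sampComp[pi] <- sampComp[pi] + nb
    }
  }
  list(snpConflicts = snpConf, sampleConflicts = sampConf,
       sampleCompared = sampComp)
}

#' Contemporary-group filtering
#'
#' Drops records in contemporary groups with fewer than `minGroupSize`
#' observations, then — in a single pass — records lying more than
#' `outlierSd` standard deviations from their group mean. Groups with zero
#' within-group variance are never trimmed.
#'
#' @param pheno phenotype data.frame (`animal`, `trait`, `cg`, `age`).
#' @param minGroupSize minimum group size (default 3).
#' @param outlierSd outlier cutoff in group SDs (default 3).
#' @return list with `phenotypes` (filtered data.frame) and `log`
#'   (data.frame of removed records with a `reason` column).
#' @export
buildContemporaryGroups <- function(pheno, minGroupSize = 3,
                                    outlierSd = 3.0) {
  stopifnot(all(c("animal", "trait", "cg") %in% names(pheno)))
  sizes <- table(pheno$cg)
  small <- names(sizes)[sizes < minGroupSize]
  drop1 <- pheno$cg %in% small
  log1 <- pheno[drop1, , drop = FALSE]
  if (nrow(log1)) log1$reason <- "small_group"
  kept <- pheno[!drop1, , drop = FALSE]

  gm <- tapply(kept$trait, kept$cg, mean)
  gs <- tapply(kept$trait, kept$cg, sd)
  dev <- abs(kept$trait - gm[kept$cg])
  lim <- outlierSd * gs[kept$cg]
  drop2 <- !is.na(lim) & lim > 0 & dev > lim
  log2 <- kept[drop2, , drop = FALSE]
  if (nrow(log2)) log2$reason <- "outlier"
  kept <- kept[!drop2, , drop = FALSE]
  if (!nrow(kept)) stop("no phenotype records remain after CG filtering")
  rownames(kept) <- NULL
  list(phenotypes = kept, log = rbind(log1, log2))
}
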