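#' Back-solve SNP effects from breeding values
#'
#' \deqn{\hat u = \frac{1}{\sum_j 2 p_j q_j} D M' G_w^{-1} \hat a}
#' where `M` is the centered dosage matrix of the genotyped animals, `D`
#' the diagonal SNP-weight matrix and `Gw` the (weighted, invertible)
#' genomic relationship matrix. With `D = I` and breeding values from an
#' all-genotyped GBLUP this recovers ridge-regression SNP-BLUP estimates.
#'
#' @param gebv breeding values of the genotyped animals (matching `M`
#'   rows).
#' @param M centered dosage matrix (see [centeredDosage]).
#' @param sumTwoPq the scaling constant `sum(2 p q)`.
#' @param d per-SNP weights (default all 1).
#' @param Gw weighted genomic relationship matrix; built as
#'   `M diag(d) M' / sumTwoPq` when omitted (supply the blended matrix for
#'   singular panels).
#' @return numeric vector of per-SNP effects (trait units / allele).
#' @export
backsolveSnpEffects <- function(gebv, M, sumTwoPq, d = NULL, Gw = NULL) {
  m <- ncol(M)
  if (length(gebv) != nrow(M)) stop("gebv length must match rows of M")
  if (is.null(d)) d <- rep(1, m)
  if (length(d) != m) stop("weight vector length must match columns of M")
  if (is.null(Gw)) Gw <- tcrossprod(sweep(M, 2, d, "*"), M) / sumTwoPq
  if (!all(dim(Gw) == nrow(M))) stop("Gw dimension mismatch")
  unname(drop(d * crossprod(M, solve(Gw, gebv)))) / sumTwoPq
}

#' Run one weighted ssGBLUP association analysis
#'
#' Executes the full iterative scheme for one analytical approach:
#' \describe{
#'   \item{UM}{unweighted, a single pass with `D = I`.}
#'   \item{QM}{quadratic weights: after each round the weight of SNP i is
#'     set to its estimated variance `uHat_i^2 * 2 p_i q_i` (or `uHat_i^2`
#'     with `qmUseFreq = FALSE`), renormalised to keep `sum(2pq d)`
#'     constant; exactly `nIter` (default 3) rounds.}
#'   \item{NLA}{non-linear A: per-SNP variances `sigmaA2 / sum(2pq) *
#'     k^(|uHat_i| / sd(uHat) - 2)` with no upper cap, renormalised the
#'     same way; iterates until the largest change in any SNP effect is
#'     below `convTol` (default 1e-4) or `nIter` (default 10) rounds.}
#' }
#' Every iteration rebuilds the weighted genomic matrix `Gw = M D M' /
#' sum(2pq)`, blends it with `A22`, rebuilds the H inverse, re-solves the
#' mixed-model equations, and back-solves SNP effects; the variance
#' components are held fixed throughout.
#'
#' @param geno a [GenotypeMatrix-class] of the genotyped animals.
#' @param ped a [Pedigree-class] containing all animals.
#' @param pheno phenotype data.frame (after CG filtering).
#' @param varcomp a [VarianceComponents-class] from [remlEstimate()].
#' @param method `"UM"`, `"QM"` or `"NLA"`.
#' @param k non-linear A constant (required for `"NLA"`; >= 1).
#' @param nIter iteration count (defaults: UM 1, QM 3, NLA 10).
#' @param convTol NLA convergence tolerance on max |change in uHat|.
#' @param alpha blending weight for G (default 0.95).
#' @param qmUseFreq logical; include `2pq` in the quadratic weight
#'   (default `TRUE`).
#' @param alleleFreq optional centering frequencies.
#' @param shared optional precomputed invariants from [gwasShared()];
#'   computed on the fly when omitted.
#' @return a [GwasRun-class].
#' @export
runGwas <- function(geno, ped, pheno, varcomp,
                    method = c("UM", "QM", "NLA"), k = NA_real_,
                    nIter = NULL, convTol = 1e-4, alpha = 0.95,
                    qmUseFreq = TRUE, alleleFreq = NULL, shared = NULL) {
  method <- match.arg(method)
  stopifnot(is(geno, "GenotypeMatrix"), is(ped, "Pedigree"),
            is(varcomp, "VarianceComponents"))
  if (method == "NLA") {
    if (is.na(k)) stop("NLA requires a weighting constant k")
    if (k < 1) stop("k must be >= 1")
  }
  if (is.null(nIter))
    nIter <- switch(method, UM = 1L, QM = 3L, NLA = 10L)
  label <- switch(method, NLA = sprintf("A_%g", k), method)

  if (is.null(shared)) shared <- gwasShared(geno, ped, pheno, alleleFreq)
  des <- shared$des
  Ainv <- shared$Ainv
  idx <- shared$idx
  A22 <- shared$A22
  A22i <- shared$A22i
  s2pq <- shared$s2pq
  M <- shared$M
  twoPq <- shared$twoPq
  sa <- varcomp@sigmaA2
  se <- varcomp@sigmaE2

  m <- ncol(M)
  dcur <- rep(1, m)
  states <- list()
  uPrev <- NULL
  ahat <- NULL
  for (it in seq_len(nIter)) {
    Gw <- tcrossprod(sweep(M, 2, dcur, "*"), M) / s2pq
    Gw <- (Gw + t(Gw)) / 2
    Gb <- blendG(Gw, A22, alpha)
    Gi <- tryCatch(solve(Gb), error = function(e)
      stop("blended G is not invertible; increase blending"))
    Hinv <- hInverseFromParts(Ainv, Gi - A22i, idx)
    sol <- solveMME(des$y, des$X, des$Zidx, Hinv, sa, se)
    ahat <- gebv(sol)[idx]
    u <- unname(drop(dcur * crossprod(M, Gi %*% ahat))) / s2pq
    snpVar <- u^2 * twoPq
    sdU <- sd(u)
    conv <- !is.null(uPrev) && max(abs(u - uPrev)) < convTol
    states[[it]] <- new("SNPWeightState", method = method, k = k,
                        iteration = as.integer(it), uHat = u,
                        snpVar = snpVar, d = dcur, sdU = sdU,
                        converged = conv)
    if (method == "UM") break
    if (method == "NLA" && conv) break
    if (it == nIter) break
    uPrev <- u
    if (method == "QM") {
      dnew <- if (qmUseFreq) snpVar else u^2
      if (all(dnew <= 0)) {
        warning("all SNP effects are zero; weights reset to 1")
        dnew <- rep(1, m)
      }
    } else { # NLA
      if (sdU == 0) {
        warning("sd(uHat) is zero; weights left equal, run flagged")
        states[[it]]@converged <- FALSE
        break
      }
      dnew <- nlaVariance(u, k, sa, s2pq)
    }
    dcur <- normalizeWeights(dnew, twoPq)
  }
  new("GwasRun", method = label, k = k, states = states,
      varcomp = varcomp, gebv = ahat)
}

#' Non-linear A SNP variance rule
#'
#' \deqn{\sigma^2_{u,i} = \frac{\sigma^2_a}{\sum_j 2 p_j q_j}
#'   \, k^{|\hat u_i| / sd(\hat u) - 2}}
#' `k = 1` gives every SNP the same baseline variance (equal weights, the
#' unweighted model); an effect two standard deviations from zero sits at
#' the exponent-zero anchor `sigmaA2 / sum(2pq)`. No upper cap is applied.
#'
#' @param uHat vector of SNP effects.
#' @param k weighting constant (>= 1).
#' @param sigmaA2 additive genetic variance.
#' @param sumTwoPq the scaling constant `sum(2pq)`.
#' @return vector of per-SNP variances (unnormalised weights).
#' @export
nlaVariance <- function(uHat, k, sigmaA2, sumTwoPq) {
  sdU <- sd(uHat)
  if (is.na(sdU) || sdU == 0) stop("sd(uHat) must be positive")
  (sigmaA2 / sumTwoPq) * k^(abs(uHat) / sdU - 2)
}

# Constant-variance normalisation: rescale d so sum(2pq * d) = sum(2pq).
normalizeWeights <- function(d, twoPq) {
  tot <- sum(twoPq * d)
  if (tot <= 0) stop("cannot normalise non-positive weights")
  d * sum(twoPq) / tot
}

#' Precompute run-invariant GWAS matrices
#'
#' Design matrices, pedigree relationship matrices and the centered dosage
#' matrix are identical across the five analytical approaches; compute
#' them once and pass to [runGwas()] via `shared`.
#'
#' @inheritParams runGwas
#' @return list used internally by [runGwas()].
#' @export
gwasShared <- function(geno, ped, pheno, alleleFreq = NULL) {
  des <- buildDesign(pheno, ped)
  A <- numeratorRelationship(ped)
  Ainv <- aInverse(ped)
  idx <- match(rownames(geno@dosage), ped@id)
  if (anyNA(idx)) stop("genotyped animal(s) absent from pedigree")
  A22 <- A[idx, idx, drop = FALSE]
  A22i <- tryCatch(solve(A22), error = function(e)
    stop("A22 is not invertible; check the pedigree of genotyped animals"))
  p <- if (is.null(alleleFreq)) geno@alleleFreq else alleleFreq
  list(des = des, A = A, Ainv = Ainv, idx = idx, A22 = A22, A22i = A22i,
       s2pq = sumTwoPq(p), M = centeredDosage(geno, p),
       twoPq = 2 * p * (1 - p))
}

#' Run the five standard analytical approaches
#'
#' Convenience wrapper running UM, QM, and non-linear A at k = 1.125, 1.2
#' and 1.5 (or any subset) with shared inputs.
#'
#' @inheritParams runGwas
#' @param methods character subset of
#'   `c("UM", "QM", "A_1.125", "A_1.2", "A_1.5")`.
#' @return named list of [GwasRun-class] objects.
#' @export
runAllGwas <- function(geno, ped, pheno, varcomp,
                       methods = c("UM", "QM", "A_1.125", "A_1.2", "A_1.5"),
                       alpha = 0.95, qmUseFreq = TRUE, alleleFreq = NULL) {
  shared <- gwasShared(geno, ped, pheno, alleleFreq)
  runs <- lapply(methods, function(mm) {
    if (mm %in% c("UM", "QM"))
      runGwas(geno, ped, pheno, varcomp, method = mm, alpha = alpha,
              qmUseFreq = qmUseFreq, alleleFreq = alleleFreq,
              shared = shared)
    else
      runGwas(geno, ped, pheno, varcomp, method = "NLA",
              k = as.numeric(sub("^A_", "", mm)), alpha = alpha,
              alleleFreq = alleleFreq, shared = shared)
  })
  setNames(runs, methods)
}

#' Per-SNP results table of a GWAS run
#'
#' @param run a [GwasRun-class].
#' @param map SNP map data.frame (`snp`, `chrom`, `pos`).
#' @return data.frame (snp, chrom, pos, uHat, snpVar, weight).
#' @export
snpEffectTable <- function(run, map) {
  st <- finalState(run)
  data.frame(snp = map$snp, chrom = map$chrom, pos = map$pos,
             uHat = st@uHat, snpVar = st@snpVar, weight = st@d,
             stringsAsFactors = FALSE)
}
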