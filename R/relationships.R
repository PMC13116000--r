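#' Numerator relationship matrix A
#'
#' Dense additive (numerator) relationship matrix by the tabular recursive
#' method, accounting for inbreeding: `a_ii = 1 + F_i`.
#'
#' @param ped a [Pedigree-class] (topologically ordered by construction).
#' @return symmetric matrix in pedigree order with pedigree ids as dimnames.
#' @export
numeratorRelationship <- function(ped) {
  stopifnot(is(ped, "Pedigree"))
  n <- length(ped@id)
  A <- matrix(0, n, n, dimnames = list(ped@id, ped@id))
  s <- ped@sire
  d <- ped@dam
  for (i in seq_len(n)) {
    if (i > 1L) {
      j <- seq_len(i - 1L)
      as_ <- if (s[i] > 0L) A[j, s[i]] else 0
      ad_ <- if (d[i] > 0L) A[j, d[i]] else 0
      aij <- 0.5 * (as_ + ad_)
      A[j, i] <- aij
      A[i, j] <- aij
    }
    A[i, i] <- 1 + if (s[i] > 0L && d[i] > 0L) 0.5 * A[s[i], d[i]] else 0
  }
  A
}

#' Inbreeding coefficients
#'
#' Per-animal inbreeding coefficients F by the Meuwissen-Luo algorithm
#' (ancestor tracing through the Cholesky factorisation A = LDL'), without
#' forming A.
#'
#' @param ped a [Pedigree-class].
#' @return named numeric vector of F in pedigree order.
#' @export
inbreeding <- function(ped) {
  stopifnot(is(ped, "Pedigree"))
  n <- length(ped@id)
  s <- ped@sire
  d <- ped@dam
  F <- numeric(n)
  Dm <- numeric(n) # Mendelian sampling variance scale
  for (i in seq_len(n)) {
    Dm[i] <- mendelianD(s[i], d[i], F)
    if (s[i] == 0L || d[i] == 0L) {
      F[i] <- 0
      next
    }
    L <- numeric(i)
    L[i] <- 1
    aii <- 0
    for (k in i:1) {
      if (L[k] == 0) next
      aii <- aii + L[k]^2 * Dm[k]
      if (s[k] > 0L) L[s[k]] <- L[s[k]] + 0.5 * L[k]
      if (d[k] > 0L) L[d[k]] <- L[d[k]] + 0.5 * L[k]
    }
    F[i] <- aii - 1
  }
  setNames(F, ped@id)
}

# Mendelian sampling variance D_i given parent knowledge and their F.
mendelianD <- function(si, di, F) {
  if (si > 0L && di > 0L) 0.5 - 0.25 * (F[si] + F[di])
  else if (si > 0L) 0.75 - 0.25 * F[si]
  else if (di > 0L) 0.75 - 0.25 * F[di]
  else 1
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding: per animal, add `1/D_i` contributions
#' to the (animal, sire, dam) block, where `D_i` is the Mendelian sampling
#' variance computed from parental inbreeding (Meuwissen-Luo).
#'
#' @param ped a [Pedigree-class].
#' @return sparse symmetric `dgCMatrix` with pedigree ids as dimnames.
#' @export
aInverse <- function(ped) {
  stopifnot(is(ped, "Pedigree"))
  n <- length(ped@id)
  F <- inbreeding(ped)
  s <- ped@sire
  d <- ped@dam
  alpha <- vapply(seq_len(n), function(i) 1 / mendelianD(s[i], d[i], F), 0)
  ti <- list(); tj <- list(); tx <- list()
  push <- function(i, j, v) {
    k <- length(ti) + 1L
    ti[[k]] <<- i; tj[[k]] <<- j; tx[[k]] <<- v
  }
  idx <- seq_len(n)
  push(idx, idx, alpha)
  for (p in list(s, d)) {
    has <- p > 0L
    push(idx[has], p[has], -0.5 * alpha[has])
    push(p[has], idx[has], -0.5 * alpha[has])
  }
  both <- cbind(s, d)
  for (a in 1:2) for (b in 1:2) {
    ha <- both[, a] > 0L
    hb <- both[, b] > 0L
    h <- ha & hb
    push(both[h, a], both[h, b], 0.25 * alpha[h])
  }
  M <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                            dims = c(n, n), dimnames = list(ped@id, ped@id))
  Matrix::forceSymmetric(M)
}

#' VanRaden genomic relationship matrix
#'
#' `G = M M' / (2 * sum(p_i q_i))` where `M` is the dosage matrix centered
#' column-wise by `2 p_i`. Missing dosages are mean-imputed to `2 p_i`
#' before centering.
#'
#' @param geno a [GenotypeMatrix-class].
#' @param alleleFreq optional centering frequencies (defaults to the
#'   frequencies stored in `geno`, i.e. observed in the genotyped set).
#' @return symmetric genomic relationship matrix with animal ids as
#'   dimnames.
#' @export
vanRadenG <- function(geno, alleleFreq = NULL) {
  stopifnot(is(geno, "GenotypeMatrix"))
  p <- if (is.null(alleleFreq)) geno@alleleFreq else alleleFreq
  if (length(p) != ncol(geno@dosage))
    stop("alleleFreq length mismatch")
  denom <- sumTwoPq(p)
  if (!is.finite(denom) || denom <= 0)
    stop("sum(2 p q) is zero: panel is monomorphic")
  M <- centeredDosage(geno, p)
  tcrossprod(M) / denom
}

# Centered SNP content matrix: missing -> 2p, then subtract 2p column-wise.
centeredDosage <- function(geno, p = NULL) {
  if (is.null(p)) p <- geno@alleleFreq
  M <- geno@dosage
  for (j in which(colSums(is.na(M)) > 0))
    M[is.na(M[, j]), j] <- 2 * p[j]
  sweep(M, 2, 2 * p, "-")
}

#' Blend the genomic relationship matrix with A22
#'
#' `G* = alpha * G + (1 - alpha) * A22`. Guarantees invertibility of a
#' singular G whenever `alpha < 1` and A22 is positive definite.
#'
#' @param Graw genomic relationship matrix.
#' @param A22 pedigree relationships among the genotyped animals, in the
#'   same order.
#' @param alpha blending weight on G (default 0.95).
#' @return blended matrix.
#' @export
blendG <- function(Graw, A22, alpha = 0.95) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (!all(dim(Graw) == dim(A22))) stop("non-conformable matrices")
  alpha * Graw + (1 - alpha) * A22
}

#' Inverse of the unified relationship matrix H
#'
#' `H^-1 = A^-1 + [0 0; 0 G*^-1 - A22^-1]`, the genotyped-block correction
#' added into the sparse pedigree inverse.
#'
#' @param Ainv sparse inverse of A (full pedigree order).
#' @param A22 pedigree relationships among genotyped animals.
#' @param Gblend blended (invertible) genomic relationship matrix.
#' @param genotypedIndex positions of the genotyped animals in pedigree
#'   order, matching the row order of `A22` / `Gblend`.
#' @return sparse symmetric H inverse.
#' @export
hInverse <- function(Ainv, A22, Gblend, genotypedIndex) {
  H <- Matrix::Matrix(Ainv, sparse = TRUE)
  if (!length(genotypedIndex)) return(Matrix::forceSymmetric(H))
  if (length(genotypedIndex) != nrow(Gblend))
    stop("genotypedIndex length must match Gblend")
  A22i <- tryCatch(solve(A22), error = function(e)
    stop("A22 is not invertible; check the pedigree of genotyped animals"))
  Gi <- tryCatch(solve(Gblend), error = function(e)
    stop("blended G is not invertible; increase blending"))
  hInverseFromParts(H, Gi - A22i, genotypedIndex)
}

# Add a dense correction block into the genotyped slice of a sparse matrix
# via triplet concatenation (indexed assignment into dgCMatrix is slow).
hInverseFromParts <- function(Ainv, corr, genotypedIndex) {
  g <- length(genotypedIndex)
  corrS <- Matrix::sparseMatrix(
    i = rep(genotypedIndex, times = g),
    j = rep(genotypedIndex, each = g),
    x = as.numeric(corr), dims = dim(Ainv), dimnames = dimnames(Ainv))
  Matrix::forceSymmetric(Matrix::drop0(Ainv + corrS))
}

#' Build all relationship matrices
#'
#' Convenience constructor for a [RelationshipSet-class]: tabular A, sparse
#' A inverse, and — when genotypes are given — A22, the (raw and blended)
#' VanRaden G, and the H inverse. With no genotypes, `Hinv` equals `Ainv`.
#'
#' @param ped a [Pedigree-class].
#' @param geno a [GenotypeMatrix-class] or `NULL`.
#' @param alpha blending weight (default 0.95).
#' @param alleleFreq optional centering frequencies for G.
#' @return a [RelationshipSet-class].
#' @export
buildRelationships <- function(ped, geno = NULL, alpha = 0.95,
                               alleleFreq = NULL) {
  A <- numeratorRelationship(ped)
  Ainv <- aInverse(ped)
  if (is.null(geno)) {
    return(new("RelationshipSet", A = A, Ainv = Ainv, A22 = NULL,
               Graw = NULL, Gblend = NULL, Hinv = Ainv,
               genotypedIndex = integer(0)))
  }
  idx <- match(rownames(geno@dosage), ped@id)
  if (anyNA(idx))
    stop("genotyped animal(s) absent from pedigree: ",
         paste(head(rownames(geno@dosage)[is.na(idx)]), collapse = ", "))
  A22 <- A[idx, idx, drop = FALSE]
  Graw <- vanRadenG(geno, alleleFreq)
  Gb <- blendG(Graw, A22, alpha)
  Hinv <- hInverse(Ainv, A22, Gb, idx)
  new("RelationshipSet", A = A, Ainv = Ainv, A22 = A22, Graw = Graw,
      Gblend = Gb, Hinv = Hinv, genotypedIndex = as.integer(idx))
}
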