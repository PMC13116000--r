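#' Build animal-model design matrices
#'
#' Response and fixed-effect design for the single-trait animal model:
#' contemporary group as a full set of indicator columns (no separate
#' intercept; the CG classes absorb it) plus age in days as a centered
#' linear covariate. The record-to-animal incidence is returned as an index
#' vector into pedigree order. Apply [buildContemporaryGroups()] first.
#'
#' @param pheno phenotype data.frame (`animal`, `trait`, `cg`, `age`).
#' @param ped a [Pedigree-class]; every phenotyped animal must appear.
#' @return list with `y`, `X` (named columns), and `Zidx` (integer,
#'   record -> pedigree position).
#' @export
buildDesign <- function(pheno, ped) {
  stopifnot(is(ped, "Pedigree"))
  idx <- match(pheno$animal, ped@id)
  if (anyNA(idx))
    stop("animal(s) in phenotypes absent from pedigree: ",
         paste(head(unique(pheno$animal[is.na(idx)])), collapse = ", "))
  cg <- factor(pheno$cg)
  X <- stats::model.matrix(~ 0 + cg)
  colnames(X) <- paste0("cg:", levels(cg))
  age <- pheno$age - mean(pheno$age)
  if (all(age == 0)) {
    warning("age covariate is constant; dropped from the design")
  } else {
    X <- cbind(X, age = age)
  }
  attr(X, "assign") <- NULL
  attr(X, "contrasts") <- NULL
  list(y = as.numeric(pheno$trait), X = X, Zidx = as.integer(idx))
}

#' Solve the animal-model mixed-model equations
#'
#' Solves
#' \deqn{[X'X, X'Z; Z'X, Z'Z + K^{-1}\lambda] [\beta; a] = [X'y; Z'y]}
#' with \eqn{\lambda = \sigma^2_e/\sigma^2_a}, by sparse Cholesky
#' factorisation. `Kinv` is the inverse relationship matrix over the full
#' pedigree (A or H inverse); breeding values are returned for every
#' pedigree animal, phenotyped or not.
#'
#' @param y,X,Zidx as returned by [buildDesign()].
#' @param Kinv sparse inverse relationship matrix (pedigree order).
#' @param sigmaA2,sigmaE2 variance components (> 0).
#' @return an [MMESolution-class].
#' @export
solveMME <- function(y, X, Zidx, Kinv, sigmaA2, sigmaE2) {
  if (sigmaA2 <= 0 || sigmaE2 <= 0) stop("variance components must be > 0")
  n <- length(y)
  nA <- nrow(Kinv)
  if (max(Zidx) > nA) stop("Zidx exceeds Kinv dimension")
  lambda <- sigmaE2 / sigmaA2
  Xs <- Matrix::Matrix(X, sparse = TRUE)
  Z <- Matrix::sparseMatrix(i = seq_len(n), j = Zidx, x = 1,
                            dims = c(n, nA))
  C <- rbind(cbind(Matrix::crossprod(Xs), Matrix::crossprod(Xs, Z)),
             cbind(Matrix::crossprod(Z, Xs),
                   Matrix::crossprod(Z) + lambda * Kinv))
  rhs <- c(as.numeric(Matrix::crossprod(Xs, y)),
           as.numeric(Matrix::crossprod(Z, y)))
  sol <- tryCatch(
    as.numeric(Matrix::solve(C, rhs)),
    error = function(e) {
      r <- tryCatch(Matrix::rankMatrix(C)[1], error = function(e2) NA)
      stop("singular mixed-model coefficient matrix (rank ", r, " of ",
           nrow(C), "); check for confounded fixed effects")
    })
  res <- as.numeric(C %*% sol) - rhs
  rn <- sqrt(sum(res^2)) / max(sqrt(sum(rhs^2)), 1e-300)
  p <- ncol(X)
  beta <- setNames(sol[seq_len(p)], colnames(X))
  a <- setNames(sol[p + seq_len(nA)], rownames(Kinv))
  new("MMESolution", betaHat = beta, gebv = a, lambda = lambda,
      solver = "direct", residualNorm = rn)
}
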