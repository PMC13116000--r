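#' REML variance components for the single-trait animal model
#'
#' Average-information REML for `y = X b + Z a + e` with `a ~ N(0, K
#' sigmaA2)` and `e ~ N(0, I sigmaE2)`, where `K` is a relationship matrix
#' (A or H). The algorithm works in the eigenbasis of the phenotyped block
#' of `K`: after one symmetric eigendecomposition every iteration costs
#' O(n p^2). Updates are Newton steps on (sigmaA2, sigmaE2) using the
#' average-information matrix; whenever an AI step proposes a component
#' below its floor (1e-8 times var(y)) an EM step is taken instead, with
#' step-halving so the restricted likelihood never decreases.
#'
#' @param y numeric response vector.
#' @param X fixed-effect design matrix (full column rank).
#' @param Z integer vector mapping each record to a row of `K` (default
#'   `seq_along(y)`).
#' @param K relationship matrix (dense, at least over the animals in `Z`).
#' @param Kinv alternatively, its (sparse) inverse over the full pedigree;
#'   inverted internally (use `K` directly when available).
#' @param init optional starting values `c(sigmaA2, sigmaE2)`; default
#'   splits `var(y)` equally.
#' @param maxIter,tol iteration cap and relative-change convergence
#'   tolerance on the components.
#' @return a [VarianceComponents-class]. Non-convergence is flagged, not an
#'   error.
#' @export
remlEstimate <- function(y, X, Z = NULL, K = NULL, Kinv = NULL,
                         init = NULL, maxIter = 200L, tol = 1e-8) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n) stop("X rows must match length(y)")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])]
    stop("X is rank deficient; confounded column(s): ",
         paste(bad, collapse = ", "))
  }
  if (is.null(Z)) Z <- seq_len(n)
  if (is.null(K)) {
    if (is.null(Kinv)) stop("one of K or Kinv is required")
    K <- as.matrix(Matrix::solve(Kinv))
  }
  K <- as.matrix(K)
  Kpp <- K[Z, Z, drop = FALSE]
  eg <- eigen((Kpp + t(Kpp)) / 2, symmetric = TRUE)
  s <- pmax(eg$values, 0)
  U <- eg$vectors
  ys <- drop(crossprod(U, y))
  Xs <- crossprod(U, X)
  vy <- var(y)
  floorv <- 1e-8 * vy
  theta <- if (is.null(init)) c(0.5, 0.5) * vy else as.numeric(init)
  theta <- pmax(theta, floorv)

  p <- ncol(X)
  eval_at <- function(th) {
    d <- pmax(th[1] * s + th[2], 1e-300)
    ViX <- Xs / d
    XtViX <- crossprod(Xs, ViX)
    cXtViX <- chol(XtViX)
    Pv <- function(v)
      v / d - ViX %*% chol2inv(cXtViX) %*% crossprod(Xs, v / d)
    Py <- drop(Pv(ys))
    ll <- -0.5 * (sum(log(d)) + 2 * sum(log(diag(cXtViX))) + sum(ys * Py))
    trP_B <- function(b) {
      # tr(P diag(b)) = tr(V^-1 b) - tr((X'V^-1X)^-1 X'V^-1 b V^-1 X)
      Cb <- crossprod(Xs, Xs * (b / d^2))
      sum(b / d) - sum(diag(chol2inv(cXtViX) %*% Cb))
    }
    list(d = d, Py = Py, Pv = Pv, ll = ll,
         trPS = trP_B(s), trPI = trP_B(rep(1, length(d))))
  }

  st <- eval_at(theta)
  trace <- data.frame(iter = integer(0), sigmaA2 = numeric(0),
                      sigmaE2 = numeric(0), loglik = numeric(0),
                      step = character(0))
  converged <- FALSE
  AI <- NULL
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    Py <- st$Py
    yPSPy <- sum(s * Py^2)
    yPPy <- sum(Py^2)
    score <- -0.5 * c(st$trPS - yPSPy, st$trPI - yPPy)
    t1 <- s * Py
    AI <- 0.5 * matrix(c(sum(t1 * st$Pv(t1)), sum(t1 * st$Pv(Py)),
                         sum(t1 * st$Pv(Py)), sum(Py * st$Pv(Py))), 2, 2)
    step <- "AI"
    delta <- tryCatch(solve(AI, score), error = function(e) NULL)
    prop <- if (is.null(delta)) rep(-1, 2) else theta + delta
    newst <- NULL
    if (any(prop < floorv)) {
      # an AI step outside the parameter space: first try projecting it
      # onto the boundary (fast exit for null components); if that loses
      # likelihood, take an EM step (guaranteed-positive update) instead
      clamped <- pmax(prop, floorv)
      clst <- eval_at(clamped)
      if (all(is.finite(clamped)) && clst$ll >= st$ll - 1e-10) {
        step <- "AI-clamped"
        prop <- clamped
        newst <- clst
      } else {
        step <- "EM"
        prop <- c(theta[1] + theta[1]^2 * (yPSPy - st$trPS) / n,
                  theta[2] + theta[2]^2 * (yPPy - st$trPI) / n)
        prop <- pmax(prop, floorv)
        # step-halving toward the current point if the likelihood drops
        newst <- eval_at(prop)
        half <- 0
        while (newst$ll < st$ll - 1e-10 && half < 30) {
          prop <- (prop + theta) / 2
          newst <- eval_at(prop)
          half <- half + 1
        }
      }
    } else {
      newst <- eval_at(prop)
      # guard AI overshoot the same way
      half <- 0
      while (newst$ll < st$ll - 1e-6 * abs(st$ll) && half < 30) {
        prop <- (prop + theta) / 2
        prop <- pmax(prop, floorv)
        newst <- eval_at(prop)
        half <- half + 1
        step <- "AI-halved"
      }
    }
    rel <- max(abs(prop - theta) / pmax(abs(theta), floorv))
    theta <- prop
    st <- newst
    trace <- rbind(trace, data.frame(iter = it, sigmaA2 = theta[1],
                                     sigmaE2 = theta[2], loglik = st$ll,
                                     step = step))
    if (rel < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("REML did not converge in ", maxIter, " iterations")
  sa <- theta[1]
  se <- theta[2]
  h <- sa / (sa + se)
  seH2 <- NA_real_
  covm <- tryCatch(solve(AI), error = function(e) NULL)
  if (!is.null(covm)) {
    g <- c(se, -sa) / (sa + se)^2
    v <- drop(t(g) %*% covm %*% g)
    if (is.finite(v) && v >= 0) seH2 <- sqrt(v)
  }
  new("VarianceComponents", sigmaA2 = sa, sigmaE2 = se, h2 = h,
      seH2 = seH2, nIterations = it, converged = converged,
      loglik = st$ll, trace = trace)
}

#' Heritability from variance components
#'
#' `h2 = sigmaA2 / (sigmaA2 + sigmaE2)`.
#'
#' @param sigmaA2 additive genetic variance (>= 0).
#' @param sigmaE2 residual variance (> 0).
#' @return narrow-sense heritability.
#' @examples
#' heritability(16.837, 48.802)  # 0.2565
#' @export
heritability <- function(sigmaA2, sigmaE2) {
  if (sigmaA2 < 0) stop("sigmaA2 must be >= 0")
  if (sigmaA2 + sigmaE2 <= 0) stop("variance components are all zero")
  if (sigmaE2 <= 0) stop("sigmaE2 must be > 0")
  sigmaA2 / (sigmaA2 + sigmaE2)
}

# Dense unified relationship matrix H (used where REML needs K = H):
# H = A + W (G* - A22) W' with W = A[, idx] A22^-1 (W restricted to the
# genotyped rows is the identity, so the genotyped block becomes G*).
computeH <- function(A, Gblend, genotypedIndex) {
  if (!length(genotypedIndex)) return(A)
  A22 <- A[genotypedIndex, genotypedIndex, drop = FALSE]
  W <- A[, genotypedIndex, drop = FALSE] %*% solve(A22)
  A + W %*% (Gblend - A22) %*% t(W)
}
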