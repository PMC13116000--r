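# Shared fixture builders. Everything is generated in code at test time.

# Unrelated sire S, dam D, child C.
trioPed <- function() {
  Pedigree(c("S", "D", "C"), c("0", "0", "S"), c("0", "0", "D"))
}

# Random multi-generation pedigree for property tests.
randomPed <- function(n = 50, nFounders = 10, seed = 1) {
  set.seed(seed)
  id <- sprintf("a%03d", seq_len(n))
  sire <- dam <- rep("0", n)
  sex <- sample(rep(c("M", "F"), length.out = n))
  for (i in (nFounders + 1):n) {
    males <- which(sex[seq_len(i - 1)] == "M")
    females <- which(sex[seq_len(i - 1)] == "F")
    if (length(males)) sire[i] <- id[sample(males, 1)]
    if (length(females)) dam[i] <- id[sample(females, 1)]
  }
  Pedigree(id, sire, dam)
}

# Binomial dosages at externally supplied frequencies (keeps G invertible
# for all-genotyped fixtures because observed means differ from 2p).
randomGeno <- function(n = 30, m = 100, seed = 1, pRange = c(0.2, 0.8),
                       ids = sprintf("a%03d", seq_len(n))) {
  set.seed(seed)
  p <- runif(m, pRange[1], pRange[2])
  dos <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m,
                dimnames = list(ids, sprintf("s%04d", seq_len(m))))
  map <- data.frame(snp = sprintf("s%04d", seq_len(m)), chrom = "1",
                    pos = seq_len(m) * 1000L, stringsAsFactors = FALSE)
  list(geno = GenotypeMatrix(dos, map, alleleFreq = p), p = p)
}

randomPheno <- function(ids, seed = 1, nCg = 3) {
  set.seed(seed)
  data.frame(animal = ids, trait = rnorm(length(ids), 10, 2),
             cg = sample(sprintf("g%d", seq_len(nCg)), length(ids),
                         replace = TRUE),
             age = sample(400:600, length(ids), replace = TRUE),
             stringsAsFactors = FALSE)
}

# Dense GLS oracle for the animal model: beta = (X'V^-1X)^-1 X'V^-1 y and
# BLUP a = sigmaA2 * A Z' V^-1 (y - X beta).
glsOracle <- function(y, X, Zidx, A, sigmaA2, sigmaE2) {
  n <- length(y)
  Z <- matrix(0, n, nrow(A))
  Z[cbind(seq_len(n), Zidx)] <- 1
  V <- Z %*% A %*% t(Z) * sigmaA2 + diag(n) * sigmaE2
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  a <- sigmaA2 * A %*% t(Z) %*% Vi %*% (y - X %*% beta)
  list(beta = drop(beta), a = drop(a))
}

# Ridge-regression SNP-BLUP oracle: joint fixed + SNP equations with
# per-SNP variance sigmaA2 / sum(2pq).
snpBlupOracle <- function(y, X, M, sigmaA2, sigmaE2, s2pq) {
  lam <- sigmaE2 / (sigmaA2 / s2pq)
  m <- ncol(M)
  C <- rbind(cbind(crossprod(X), crossprod(X, M)),
             cbind(crossprod(M, X), crossprod(M) + lam * diag(m)))
  sol <- solve(C, c(crossprod(X, y), crossprod(M, y)))
  u <- sol[(ncol(X) + 1):length(sol)]
  list(beta = sol[seq_len(ncol(X))], u = u, gebv = drop(M %*% u))
}

# A small Ensembl-style GTF written to a temp file; returns path and the
# gene table for brute-force comparison.
writeToyGtf <- function(genes, path = tempfile(fileext = ".gtf")) {
  lines <- sprintf(
    '%s\ttoy\tgene\t%d\t%d\t.\t+\t.\tgene_id "%s"; gene_name "%s";',
    genes$chrom, genes$start, genes$end, genes$geneId, genes$symbol)
  writeLines(lines, path)
  path
}

writeToyGmt <- function(sets, path = tempfile(fileext = ".gmt")) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  path
}

# The fixed oligogenic study fixture: 5 QTL carrying 30% of the additive
# variance, 1000 genotyped + phenotyped final-generation animals.
oligogenicConfig <- function(seed = 42) {
  simulationConfig(nFounders = 250, nGenerations = 2,
                   offspringPerMating = 4, nChromosomes = 10,
                   nSnpsPerChromosome = 100, nQtl = 5,
                   qtlVarianceFraction = 0.30, traitH2 = 0.30,
                   genotypedFraction = 1.0, missingGenotypeRate = 0,
                   seed = seed)
}
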