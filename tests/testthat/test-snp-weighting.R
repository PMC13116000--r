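# Shared small weighted-GWAS fixture: all-genotyped two-generation
# population with one strong QTL, used across the iteration tests.
weightFixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- simulationConfig(nFounders = 60L, nGenerations = 2L,
                            offspringPerMating = 4L, nChromosomes = 3L,
                            nSnpsPerChromosome = 60L, nQtl = 1L,
                            qtlVarianceFraction = 0.6, traitH2 = 0.4,
                            genotypedFraction = 1, missingGenotypeRate = 0,
                            seed = 202)
    ds <- simulateDataset(cfg)
    vc <- new("VarianceComponents", sigmaA2 = 0.4, sigmaE2 = 0.6,
              h2 = 0.4, seH2 = NA_real_, nIterations = 1L,
              converged = TRUE, loglik = 0,
              trace = data.frame())
    cache <<- list(ds = ds, vc = vc)
    cache
  }
})

test_that("back-solved SNP effects obey linearity and scale invariance", {
  rg <- randomGeno(n = 30, m = 80, seed = 31)
  M <- dosageMatrix(rg$geno) - matrix(2 * rg$p, 30, 80, byrow = TRUE)
  s2pq <- sum(2 * rg$p * (1 - rg$p))
  expect_equal(backsolveSnpEffects(rep(0, 30), M, s2pq), rep(0, 80))

  set.seed(31)
  a <- rnorm(30)
  d <- runif(80, 0.5, 2)
  u1 <- backsolveSnpEffects(a, M, s2pq, d = d)
  u2 <- backsolveSnpEffects(a, M, s2pq, d = 2 * d)
  # doubling D and rebuilding Gw consistently leaves fitted values intact
  expect_lt(max(abs(drop(M %*% u1) - drop(M %*% u2))), 1e-6)
  expect_error(backsolveSnpEffects(a[-1], M, s2pq), "length")
})

test_that("unweighted run computes snp variances as uHat^2 * 2pq", {
  fx <- weightFixture()
  run <- runGwas(fx$ds@genotypes, fx$ds@pedigree, fx$ds@phenotypes,
                 fx$vc, method = "UM")
  st <- finalState(run)
  p <- alleleFreq(fx$ds@genotypes)
  expect_identical(st@snpVar, st@uHat^2 * (2 * p * (1 - p)))
  expect_true(all(st@d == 1))
  expect_length(iterationStates(run), 1L)
  # fitted genetic values of genotyped animals track their GEBVs
  M <- wssgblup:::centeredDosage(fx$ds@genotypes)
  expect_gt(cor(drop(M %*% st@uHat), gebv(run)), 0.98)
})

test_that("quadratic weighting shares its first step with UM and then reweights", {
  fx <- weightFixture()
  um <- runGwas(fx$ds@genotypes, fx$ds@pedigree, fx$ds@phenotypes,
                fx$vc, method = "UM")
  qm <- runGwas(fx$ds@genotypes, fx$ds@pedigree, fx$ds@phenotypes,
                fx$vc, method = "QM")
  expect_length(iterationStates(qm), 3L)
  expect_identical(iterationStates(qm)[[1]]@uHat, finalState(um)@uHat)
  expect_identical(iterationStates(qm)[[1]]@snpVar, finalState(um)@snpVar)

  # the QTL SNP's weight strictly increases over the iterations
  qtl <- fx$ds@truth$qtlSnp
  w <- vapply(iterationStates(qm), function(s) s@d[qtl], 0)
  expect_true(all(diff(w) > 0))
  # and the constant-variance constraint holds after every iteration
  p <- alleleFreq(fx$ds@genotypes)
  twoPq <- 2 * p * (1 - p)
  for (s in iterationStates(qm))
    expect_lt(abs(sum(twoPq * s@d) - sum(twoPq)), 1e-8 * sum(twoPq))
})

test_that("non-linear A with k = 1 reproduces the unweighted analysis exactly", {
  fx <- weightFixture()
  um <- runGwas(fx$ds@genotypes, fx$ds@pedigree, fx$ds@phenotypes,
                fx$vc, method = "UM")
  nla1 <- runGwas(fx$ds@genotypes, fx$ds@pedigree, fx$ds@phenotypes,
                  fx$vc, method = "NLA", k = 1)
  expect_identical(finalState(nla1)@uHat, finalState(um)@uHat)
  expect_identical(finalState(nla1)@snpVar, finalState(um)@snpVar)
  expect_true(finalState(nla1)@converged)
  expect_lte(length(iterationStates(nla1)), 2L)
})

test_that("the non-linear A variance rule has its documented anchors", {
  u <- c(-0.4, 0.1, 0.2, 0.8)
  sdu <- sd(u)
  v <- nlaVariance(u, 1.2, sigmaA2 = 2, sumTwoPq = 50)
  expect_equal(v, (2 / 50) * 1.2^(abs(u) / sdu - 2))
  # exponent-zero anchor: an effect at exactly 2 sd(u) gets the baseline
  # variance sigmaA2 / sum(2pq); u = c(2, 2 - sqrt(2)) has sd 1
  u2 <- c(2, 2 - sqrt(2))
  expect_equal(sd(u2), 1)
  expect_equal(nlaVariance(u2, 1.5, 2, 50)[1], 2 / 50)
  expect_true(all(nlaVariance(u, 1, 2, 50) == 2 / 50))
  expect_error(nlaVariance(rep(1, 4), 1.2, 2, 50), "positive")
})

test_that("larger k concentrates more window variance on the QTL", {
  fx <- weightFixture()
  lo <- runGwas(fx$ds@genotypes, fx$ds@pedigree, fx$ds@phenotypes,
                fx$vc, method = "NLA", k = 1.125)
  hi <- runGwas(fx$ds@genotypes, fx$ds@pedigree, fx$ds@phenotypes,
                fx$vc, method = "NLA", k = 1.5)
  grid <- defineWindows(snpMap(fx$ds@genotypes), 20)
  wlo <- windowVariances(grid, snpVariances(lo), 0.4)
  whi <- windowVariances(grid, snpVariances(hi), 0.4)
  expect_gt(max(whi$varPct), max(wlo$varPct))
})

test_that("weighted runs are deterministic and respect iteration caps", {
  fx <- weightFixture()
  r1 <- runGwas(fx$ds@genotypes, fx$ds@pedigree, fx$ds@phenotypes,
                fx$vc, method = "NLA", k = 1.2)
  r2 <- runGwas(fx$ds@genotypes, fx$ds@pedigree, fx$ds@phenotypes,
                fx$vc, method = "NLA", k = 1.2)
  expect_identical(snpEffects(r1), snpEffects(r2))
  expect_lte(length(iterationStates(r1)), 10L)
  expect_equal(r1@method, "A_1.2")

  tab <- snpEffectTable(r1, snpMap(fx$ds@genotypes))
  expect_equal(names(tab), c("snp", "chrom", "pos", "uHat", "snpVar",
                             "weight"))
  expect_equal(nrow(tab), nSnps(fx$ds@genotypes))
})

test_that("weight normalisation keeps total genetic variance constant", {
  set.seed(33)
  twoPq <- runif(50, 0.1, 0.5)
  d <- rexp(50)
  dn <- wssgblup:::normalizeWeights(d, twoPq)
  expect_equal(sum(twoPq * dn), sum(twoPq), tolerance = 1e-12)
  # equal effects and frequencies stay at equal weights
  expect_equal(wssgblup:::normalizeWeights(rep(3, 10), rep(0.4, 10)),
               rep(1, 10))
})
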