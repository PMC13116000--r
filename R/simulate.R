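#' Create a simulation configuration
#'
#' Returns a validated [SimulationConfig-class]. Defaults describe a
#' desk-scale population with the structure the analysis model assumes:
#' 300 founders and 3 discrete generations of random mating, a genome of 30
#' chromosomes of 1 Morgan carrying 60 evenly spaced SNPs each, a trait
#' with heritability 0.26 controlled by 20 QTL (30% of the additive
#' variance) plus a pedigree polygene, 64 contemporary groups, a linear age
#' effect, and genotypes for about half of the final-generation animals
#' with 1% missing dosages.
#'
#' @param nFounders,nGenerations,offspringPerMating population structure;
#'   each generation mates random sire/dam pairs drawn from the previous
#'   one, every pair leaving `offspringPerMating` offspring.
#' @param nChromosomes,chromosomeLengthMorgans,nSnpsPerChromosome genome.
#' @param founderMafRange per-SNP founder allele frequencies are drawn
#'   uniformly from this range (then randomly assigned to either allele).
#' @param nQtl,traitH2,qtlVarianceFraction genetic architecture; total
#'   additive variance is `traitH2` on a phenotypic scale of 1 (before
#'   fixed effects), split `qtlVarianceFraction` : (1 -
#'   `qtlVarianceFraction`) between explicit QTL and the polygene.
#' @param nCg,cgEffectSd,ageRangeDays,ageSlope fixed-effect structure.
#' @param genotypedFraction fraction of final-generation animals genotyped.
#' @param missingGenotypeRate uniform missing-dosage rate.
#' @param seed RNG seed; fully determines all output.
#' @return a [SimulationConfig-class].
#' @export
simulationConfig <- function(nFounders = 300L, nGenerations = 3L,
                             offspringPerMating = 2L, nChromosomes = 30L,
                             chromosomeLengthMorgans = 1.0,
                             nSnpsPerChromosome = 60L,
                             founderMafRange = c(0.05, 0.5), nQtl = 20L,
                             traitH2 = 0.26, qtlVarianceFraction = 0.30,
                             nCg = 64L, cgEffectSd = 0.5,
                             ageRangeDays = c(400L, 640L),
                             ageSlope = 0.005,
                             genotypedFraction = 0.5,
                             missingGenotypeRate = 0.01, seed = 1L) {
  new("SimulationConfig",
      nFounders = as.integer(nFounders),
      nGenerations = as.integer(nGenerations),
      offspringPerMating = as.integer(offspringPerMating),
      nChromosomes = as.integer(nChromosomes),
      chromosomeLengthMorgans = chromosomeLengthMorgans,
      nSnpsPerChromosome = as.integer(nSnpsPerChromosome),
      founderMafRange = founderMafRange, nQtl = as.integer(nQtl),
      traitH2 = traitH2, qtlVarianceFraction = qtlVarianceFraction,
      nCg = as.integer(nCg), cgEffectSd = cgEffectSd,
      ageRangeDays = as.integer(ageRangeDays), ageSlope = ageSlope,
      genotypedFraction = genotypedFraction,
      missingGenotypeRate = missingGenotypeRate, seed = as.integer(seed))
}

#' Simulate a pedigree
#'
#' Discrete-generation random mating: founders have unknown parents; each
#' later generation is produced by pairing the previous generation into
#' sire/dam couples (half of each generation is male), each couple leaving
#' `offspringPerMating` offspring. Record order is generation order, so
#' parents always precede offspring.
#'
#' @param config a [SimulationConfig-class].
#' @return list with `pedigree` (a [Pedigree-class]), `generation` (integer
#'   per animal) and `sex` (`"M"`/`"F"` per animal).
#' @export
simulatePedigree <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  if (config@nFounders < 1L) stop("need at least one founder")
  set.seed(config@seed)
  id <- sprintf("G0_%04d", seq_len(config@nFounders))
  sire <- rep("0", config@nFounders)
  dam <- rep("0", config@nFounders)
  gen <- rep(0L, config@nFounders)
  sex <- rep(c("M", "F"), length.out = config@nFounders)
  prev <- id
  prev_sex <- sex
  for (g in seq_len(config@nGenerations)) {
    males <- sample(prev[prev_sex == "M"])
    females <- sample(prev[prev_sex == "F"])
    nm <- min(length(males), length(females))
    if (nm == 0L) break
    off_s <- rep(males[seq_len(nm)], each = config@offspringPerMating)
    off_d <- rep(females[seq_len(nm)], each = config@offspringPerMating)
    noff <- length(off_s)
    off_id <- sprintf("G%d_%04d", g, seq_len(noff))
    off_sex <- sample(rep(c("M", "F"), length.out = noff))
    id <- c(id, off_id)
    sire <- c(sire, off_s)
    dam <- c(dam, off_d)
    gen <- c(gen, rep(g, noff))
    sex <- c(sex, off_sex)
    prev <- off_id
    prev_sex <- off_sex
  }
  ped <- Pedigree(id, sire, dam)
  ord <- match(ped@id, id)
  list(pedigree = ped, generation = gen[ord], sex = sex[ord])
}

#' Gene-drop SNP genotypes through a pedigree
#'
#' Founder haplotype alleles are drawn per SNP at a frequency sampled from
#' `founderMafRange`; offspring gametes are formed by meiosis with a
#' Poisson number of crossovers per chromosome (expectation =
#' `chromosomeLengthMorgans`, i.e. the Haldane no-interference map) at
#' uniform positions. Missing dosages are introduced uniformly at
#' `missingGenotypeRate`. Genotypes are simulated for every pedigree animal
#' and subset afterwards by the caller.
#'
#' @param ped a [Pedigree-class].
#' @param config a [SimulationConfig-class].
#' @param keep optional character ids to retain in the returned matrix.
#' @param missingRate missing-dosage rate (defaults to the config value).
#' @return a [GenotypeMatrix-class].
#' @export
simulateGenotypes <- function(ped, config, keep = NULL,
                              missingRate = config@missingGenotypeRate) {
  stopifnot(is(ped, "Pedigree"), is(config, "SimulationConfig"))
  set.seed(config@seed + 1L)
  n <- length(ped@id)
  nchr <- config@nChromosomes
  mper <- config@nSnpsPerChromosome
  Lm <- config@chromosomeLengthMorgans
  chromLabels <- c(as.character(seq_len(max(nchr - 1L, 1L))),
                   if (nchr > 1L) "X")
  chromLabels <- chromLabels[seq_len(nchr)]
  # evenly spaced SNPs; 1 Morgan ~ 100 Mb so window spans are bp-meaningful
  bp_per_chr <- max(round(1e8 * Lm), mper)
  pos <- round(seq(1, bp_per_chr, length.out = mper))
  hap1 <- matrix(0L, n, nchr * mper)
  hap2 <- matrix(0L, n, nchr * mper)
  map <- data.frame(
    snp = sprintf("snp_%s_%04d", rep(chromLabels, each = mper),
                  rep(seq_len(mper), nchr)),
    chrom = rep(chromLabels, each = mper),
    pos = rep(pos, nchr), stringsAsFactors = FALSE)
  pfound <- runif(nchr * mper, config@founderMafRange[1],
                  config@founderMafRange[2])
  flip <- runif(nchr * mper) < 0.5
  pfound[flip] <- 1 - pfound[flip]
  founders <- which(ped@sire == 0L & ped@dam == 0L)
  m <- nchr * mper
  hap1[founders, ] <- matrix(
    rbinom(length(founders) * m, 1L, rep(pfound, each = length(founders))),
    length(founders), m)
  hap2[founders, ] <- matrix(
    rbinom(length(founders) * m, 1L, rep(pfound, each = length(founders))),
    length(founders), m)
  chrIdx <- lapply(seq_len(nchr), function(c) (c - 1L) * mper + seq_len(mper))
  posM <- (pos / bp_per_chr) * Lm  # map positions in Morgans
  gamete <- function(h1, h2) {
    out <- integer(m)
    for (c in seq_len(nchr)) {
      ix <- chrIdx[[c]]
      ncx <- rpois(1L, Lm)
      start <- sample(1:2, 1L)
      if (ncx == 0L || Lm == 0) {
        out[ix] <- if (start == 1L) h1[ix] else h2[ix]
      } else {
        cx <- sort(runif(ncx, 0, Lm))
        seg <- findInterval(posM, cx)  # segment index per SNP
        use1 <- (seg + start) %% 2L == 1L
        out[ix] <- ifelse(use1, h1[ix], h2[ix])
      }
    }
    out
  }
  nonfounders <- setdiff(seq_len(n), founders)
  for (i in nonfounders) {
    s <- ped@sire[i]
    d <- ped@dam[i]
    hap1[i, ] <- if (s > 0L) gamete(hap1[s, ], hap2[s, ]) else
      rbinom(m, 1L, pfound)
    hap2[i, ] <- if (d > 0L) gamete(hap1[d, ], hap2[d, ]) else
      rbinom(m, 1L, pfound)
  }
  dos <- hap1 + hap2
  rownames(dos) <- ped@id
  if (!is.null(keep)) dos <- dos[keep, , drop = FALSE]
  storage.mode(dos) <- "double"
  if (missingRate > 0) {
    miss <- runif(length(dos)) < missingRate
    dos[miss] <- NA_real_
  }
  GenotypeMatrix(dos, map)
}

#' Simulate phenotypes with known truth
#'
#' True breeding values are the sum of an explicit-QTL part (QTL dosages
#' times effects, scaled so its realised variance is `qtlVarianceFraction *
#' sigmaA2True`) and a pedigree polygene sampled by Mendelian-sampling
#' recursion from `N(0, A * sigmaPoly2)`. Phenotype = CG effect +
#' `ageSlope * age` + TBV + residual. The phenotypic scale (TBV + residual)
#' is 1, so `sigmaA2True = traitH2`.
#'
#' @param ped a [Pedigree-class].
#' @param geno a [GenotypeMatrix-class] covering all pedigree animals, or
#'   `NULL` (allowed when `qtlVarianceFraction = 0`).
#' @param config a [SimulationConfig-class].
#' @param phenotyped character ids of animals to phenotype (default: all).
#' @return list with `phenotypes` (data.frame animal/trait/cg/age) and
#'   `truth` (list: `tbv`, `qtlSnp`, `qtlEffect`, `sigmaA2True`,
#'   `sigmaE2True`).
#' @export
simulatePhenotypes <- function(ped, geno, config, phenotyped = NULL) {
  stopifnot(is(ped, "Pedigree"), is(config, "SimulationConfig"))
  set.seed(config@seed + 2L)
  n <- length(ped@id)
  sigmaA2 <- config@traitH2
  sigmaE2 <- 1 - config@traitH2
  fracQ <- if (config@nQtl > 0L) config@qtlVarianceFraction else 0
  if (fracQ > 0 && is.null(geno))
    stop("genotypes required when qtlVarianceFraction > 0")
  qtlSnp <- integer(0)
  qtlEffect <- numeric(0)
  tbvQ <- numeric(n)
  if (fracQ > 0 && sigmaA2 > 0) {
    m <- ncol(geno@dosage)
    if (config@nQtl > m) stop("more QTL requested than SNPs available")
    qtlSnp <- sort(sample.int(m, config@nQtl))
    qtlEffect <- rnorm(config@nQtl)
    D <- geno@dosage[ped@id, qtlSnp, drop = FALSE]
    D[is.na(D)] <- 0
    raw <- drop(D %*% qtlEffect)
    v <- var(raw)
    if (v > 0) {
      scale <- sqrt(fracQ * sigmaA2 / v)
      qtlEffect <- qtlEffect * scale
      tbvQ <- (raw - mean(raw)) * scale
    }
  }
  sigmaPoly <- sigmaA2 * (1 - fracQ)
  tbvP <- numeric(n)
  if (sigmaPoly > 0) {
    F <- inbreeding(ped)
    for (i in seq_len(n)) {
      s <- ped@sire[i]
      d <- ped@dam[i]
      mid <- (if (s > 0L) tbvP[s] else 0) / 2 +
        (if (d > 0L) tbvP[d] else 0) / 2
      vm <- mendelianD(s, d, F) * sigmaPoly
      tbvP[i] <- mid + rnorm(1L, 0, sqrt(vm))
    }
  }
  tbv <- setNames(tbvQ + tbvP, ped@id)
  if (is.null(phenotyped)) phenotyped <- ped@id
  np <- length(phenotyped)
  cg <- sprintf("cg%02d", sample.int(config@nCg, np, replace = TRUE))
  cgEff <- setNames(rnorm(config@nCg, 0, config@cgEffectSd),
                    sprintf("cg%02d", seq_len(config@nCg)))
  age <- sample(seq(config@ageRangeDays[1], config@ageRangeDays[2]), np,
                replace = TRUE)
  e <- rnorm(np, 0, sqrt(sigmaE2))
  yval <- cgEff[cg] + config@ageSlope * age + tbv[phenotyped] + e
  pheno <- data.frame(animal = phenotyped, trait = unname(yval), cg = cg,
                      age = as.integer(age), stringsAsFactors = FALSE)
  list(phenotypes = pheno,
       truth = list(tbv = tbv, qtlSnp = qtlSnp, qtlEffect = qtlEffect,
                    sigmaA2True = sigmaA2, sigmaE2True = sigmaE2,
                    cgEffects = cgEff))
}

#' Simulate a complete dataset
#'
#' Runs [simulatePedigree()], [simulateGenotypes()] and
#' [simulatePhenotypes()] under one seed. Final-generation animals are
#' phenotyped; a random `genotypedFraction` of them (plus their genotyped
#' status) forms the genotype matrix. When `qtlVarianceFraction = 0` and
#' `genotype = FALSE`, genotype simulation is skipped entirely.
#'
#' @param config a [SimulationConfig-class].
#' @param genotype logical; simulate genotypes (default `TRUE`).
#' @return a [SimulatedDataset-class].
#' @export
simulateDataset <- function(config, genotype = TRUE) {
  sim <- simulatePedigree(config)
  ped <- sim$pedigree
  lastGen <- max(sim$generation)
  phenotyped <- ped@id[sim$generation == lastGen]
  genoAll <- NULL
  genoSub <- NULL
  if (genotype) {
    # truth uses complete dosages; missingness only affects the observed
    # genotype matrix of the genotyped subset
    genoAll <- simulateGenotypes(ped, config, missingRate = 0)
    set.seed(config@seed + 3L)
    ng <- max(1L, round(config@genotypedFraction * length(phenotyped)))
    gids <- sort(sample(phenotyped, ng))
    keep <- match(gids, rownames(genoAll@dosage))
    dsub <- genoAll@dosage[keep, , drop = FALSE]
    if (config@missingGenotypeRate > 0) {
      miss <- runif(length(dsub)) < config@missingGenotypeRate
      dsub[miss] <- NA_real_
    }
    genoSub <- GenotypeMatrix(dsub, genoAll@map)
  } else if (config@qtlVarianceFraction > 0 && config@nQtl > 0L &&
             config@traitH2 > 0) {
    stop("cannot skip genotypes with explicit QTL variance")
  }
  phe <- simulatePhenotypes(ped, genoAll, config, phenotyped = phenotyped)
  new("SimulatedDataset", pedigree = ped, genotypes = genoSub,
      phenotypes = phe$phenotypes, truth = phe$truth)
}

#' Write a simulated dataset to TSV files
#'
#' Writes `pedigree.tsv`, `genotypes.tsv`, `map.tsv`, `phenotypes.tsv` and
#' `truth.tsv` (per-animal true breeding values) in the formats the reader
#' functions accept.
#'
#' @param dataset a [SimulatedDataset-class].
#' @param dir output directory (created if absent).
#' @return the directory, invisibly.
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writePedigree(dataset@pedigree, file.path(dir, "pedigree.tsv"))
  if (!is.null(dataset@genotypes))
    writeGenotypes(dataset@genotypes, file.path(dir, "genotypes.tsv"),
                   file.path(dir, "map.tsv"))
  writePhenotypes(dataset@phenotypes, file.path(dir, "phenotypes.tsv"))
  writeTsv(data.frame(animal = names(dataset@truth$tbv),
                      tbv = unname(dataset@truth$tbv)),
           file.path(dir, "truth.tsv"))
  invisible(dir)
}
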