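#' Default pipeline settings
#'
#' One place for every analysis constant: QC thresholds (call rates 0.90,
#' MAF 0.05, sample Mendelian conflict rate 0.02), CG rules (minimum 3
#' records, 3 SD outliers), blending alpha 0.95, 20-SNP windows, 0.5%
#' variance threshold, 500 kb flanks, QM at 3 iterations, non-linear A at
#' 10 iterations with k in {1.125, 1.2, 1.5} and convergence 1e-4.
#'
#' @return named list of defaults, overridable via [runPipeline()]'s
#'   config.
#' @export
pipelineDefaults <- function() {
  list(
    seed = 1L,
    simulate = NULL,        # list of simulationConfig() arguments, or NULL
    paths = list(pedigree = NULL, genotypes = NULL, map = NULL,
                 phenotypes = NULL, gtf = NULL, gmt = NULL),
    qc = list(sampleCallMin = 0.90, snpCallMin = 0.90, mafMin = 0.05,
              mendelSampleRate = 0.02),
    cg = list(minGroupSize = 3, outlierSd = 3.0),
    alpha = 0.95,
    methods = c("UM", "QM", "A_1.125", "A_1.2", "A_1.5"),
    windowSize = 20L,
    thresholdPct = 0.5,
    flankBp = 500000L,
    nlaIter = 10L,
    qmIter = 3L,
    convTol = 1e-4)
}

#' Run the full weighted ssGBLUP association pipeline
#'
#' Orchestrates the analysis end to end: data input (simulation or files),
#' genotype QC, contemporary-group filtering, relationship matrices, REML
#' variance components under H, the selected weighted GWAS approaches,
#' window variance partitioning, the variance threshold, recurrence
#' classification and, when a GTF / GMT is supplied, gene annotation of
#' recurrent regions and per-approach over-representation analysis of all
#' significant windows' genes.
#'
#' @param config named list overriding [pipelineDefaults()], or the path
#'   to a YAML file with the same structure. Set `simulate` to a list of
#'   [simulationConfig()] arguments to generate data, or fill `paths`.
#' @param outDir optional directory; when given, every stage's tables are
#'   written as TSV plus a `manifest.yaml`.
#' @return (invisibly) list with elements `data`, `qcReport`, `varcomp`,
#'   `runs`, `windows`, `significant`, `recurrence`, `upset`,
#'   `annotation`, `enrichment`.
#' @export
runPipeline <- function(config = list(), outDir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(pipelineDefaults(), config)
  t0 <- Sys.time()
  timings <- c()
  tick <- function(stage) {
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    t0 <<- Sys.time()
  }

  # --- data ---
  if (!is.null(cfg$simulate)) {
    simArgs <- cfg$simulate
    if (isTRUE(simArgs)) simArgs <- list()
    if (is.null(simArgs$seed)) simArgs$seed <- cfg$seed
    simCfg <- do.call(simulationConfig, simArgs)
    ds <- simulateDataset(simCfg)
    ped <- ds@pedigree
    geno <- ds@genotypes
    pheno <- ds@phenotypes
  } else {
    p <- cfg$paths
    if (is.null(p$pedigree) || is.null(p$phenotypes))
      stop("config must provide simulate settings or input paths")
    ped <- readPedigree(p$pedigree)
    geno <- if (!is.null(p$genotypes)) readGenotypes(p$genotypes, p$map)
    pheno <- readPhenotypes(p$phenotypes)
    ds <- NULL
  }
  tick("data")

  # --- QC ---
  qcRes <- qcFilter(geno, ped,
                    sampleCallMin = cfg$qc$sampleCallMin,
                    snpCallMin = cfg$qc$snpCallMin,
                    mafMin = cfg$qc$mafMin,
                    mendelSampleRate = cfg$qc$mendelSampleRate)
  geno <- qcRes$genotypes
  cgRes <- buildContemporaryGroups(pheno, cfg$cg$minGroupSize,
                                   cfg$cg$outlierSd)
  pheno <- cgRes$phenotypes
  tick("qc")

  # --- relationships + REML (H-based when genotypes are present) ---
  rel <- buildRelationships(ped, geno, alpha = cfg$alpha)
  K <- if (length(rel@genotypedIndex))
    computeH(rel@A, rel@Gblend, rel@genotypedIndex) else rel@A
  des <- buildDesign(pheno, ped)
  vc <- remlEstimate(des$y, des$X, Z = des$Zidx, K = K)
  tick("reml")

  # --- weighted GWAS runs ---
  runs <- runAllGwas(geno, ped, pheno, vc, methods = cfg$methods,
                     alpha = cfg$alpha)
  tick("gwas")

  # --- windows, threshold, recurrence ---
  grid <- defineWindows(snpMap(geno), cfg$windowSize)
  winAll <- lapply(runs, function(r)
    windowVariances(grid, snpVariances(r), sigmaA2(vc)))
  winSig <- lapply(winAll, significantWindows, thresholdPct = cfg$thresholdPct)
  rec <- recurrenceClassify(winSig)
  tick("windows")

  # --- annotation of recurrent (>= 2 approaches) regions ---
  annot <- NULL
  enrich <- NULL
  gtfPath <- cfg$paths$gtf
  if (!is.null(gtfPath)) {
    genes <- readGtfGenes(gtfPath)
    recWin <- rec$recurrence[rec$recurrence$nMethods >= 2, , drop = FALSE]
    recWin <- merge(recWin[, c("key", "nMethods", "klass")],
                    grid, by = "key")
    annot <- annotateRegions(recWin, genes, flankBp = cfg$flankBp)
    if (!is.null(cfg$paths$gmt)) {
      sets <- readGmt(cfg$paths$gmt)
      universe <- unique(S4Vectors::mcols(genes)$gene_id)
      perMethodGenes <- lapply(winSig, function(w)
        unique(annotateRegions(w, genes, flankBp = cfg$flankBp)$geneId))
      enrichTabs <- lapply(perMethodGenes, function(g)
        hypergeometricEnrichment(g, sets, universe))
      enrich <- list(perMethod = enrichTabs,
                     recurrence = compareAcrossMethods(enrichTabs))
    }
  }
  tick("annotation")

  out <- list(data = ds, pedigree = ped, genotypes = geno,
              phenotypes = pheno, qcReport = qcRes$report, varcomp = vc,
              runs = runs, windows = winAll, significant = winSig,
              recurrence = rec$recurrence, upset = rec$upset,
              annotation = annot, enrichment = enrich,
              timings = unlist(timings), config = cfg)

  if (!is.null(outDir)) writePipelineOutputs(out, geno, outDir)
  invisible(out)
}

writePipelineOutputs <- function(out, geno, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  vc <- out$varcomp
  writeTsv(data.frame(sigmaA2 = sigmaA2(vc), sigmaE2 = sigmaE2(vc),
                      h2 = h2(vc), seH2 = vc@seH2,
                      converged = vc@converged), file.path(outDir,
                                                           "varcomp.tsv"))
  for (mm in names(out$runs)) {
    safe <- gsub("[^A-Za-z0-9_.]", "_", mm)
    writeTsv(snpEffectTable(out$runs[[mm]], snpMap(geno)),
             file.path(outDir, paste0("snp_effects_", safe, ".tsv")))
    writeTsv(out$windows[[mm]],
             file.path(outDir, paste0("windows_", safe, ".tsv")))
  }
  writeTsv(out$recurrence, file.path(outDir, "recurrence.tsv"))
  writeTsv(out$upset, file.path(outDir, "upset_counts.tsv"))
  if (!is.null(out$annotation))
    writeTsv(out$annotation, file.path(outDir, "annotated_genes.tsv"))
  if (!is.null(out$enrichment))
    for (mm in names(out$enrichment$perMethod)) {
      safe <- gsub("[^A-Za-z0-9_.]", "_", mm)
      writeTsv(out$enrichment$perMethod[[mm]],
               file.path(outDir, paste0("enrichment_", safe, ".tsv")))
    }
  manifest <- list(config = rapply(out$config, as.vector, how = "replace"),
                   timingsSec = as.list(round(out$timings, 3)),
                   rVersion = R.version.string,
                   packageVersion =
                     as.character(utils::packageVersion("wssgblup")))
  yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
  invisible(outDir)
}
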