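test_that("window partition keeps chromosome boundaries and remainders", {
  map <- data.frame(snp = sprintf("s%02d", 1:43), chrom = "1",
                    pos = seq_len(43) * 1000L)
  w <- defineWindows(map, 20)
  expect_equal(nrow(w), 3L)
  expect_equal(w$nSnps, c(20L, 20L, 3L))
  expect_equal(w$full, c(TRUE, TRUE, FALSE))

  # 20 SNPs spanning 1 Mb -> one window with that physical span
  map2 <- data.frame(snp = sprintf("t%02d", 1:20), chrom = "5",
                     pos = as.integer(seq(1, 1e6, length.out = 20)))
  w2 <- defineWindows(map2, 20)
  expect_equal(nrow(w2), 1L)
  expect_equal(w2$bpEnd - w2$bpStart + 1, 1e6)

  # windows never cross chromosomes
  map3 <- rbind(transform(map[1:25, ], chrom = "1"),
                transform(map[1:25, ], chrom = "2",
                          snp = sprintf("u%02d", 1:25)))
  w3 <- defineWindows(map3, 20)
  expect_equal(w3$chrom, c("1", "1", "2", "2"))
  expect_equal(w3$nSnps, c(20L, 5L, 20L, 5L))
  expect_error(defineWindows(map[0, ]), "empty")
})

test_that("window variances conserve the SNP variance total", {
  set.seed(41)
  map <- data.frame(snp = sprintf("s%03d", 1:137),
                    chrom = rep(c("1", "2", "X"), c(60, 50, 27)),
                    pos = as.integer(c(seq_len(60), seq_len(50),
                                       seq_len(27)) * 777L))
  w <- defineWindows(map, 20)
  for (i in 1:5) {
    sv <- rexp(137)
    wf <- windowVariances(w, sv, sigmaA2 = 2.5)
    expect_equal(sum(wf$varAbs), sum(sv), tolerance = 1e-10)
    expect_equal(wf$varPct, 100 * wf$varAbs / 2.5)
  }
  wf <- windowVariances(w, rep(0, 137), 1)
  expect_true(all(wf$varPct == 0))
})

test_that("the 0.5% threshold is inclusive at the boundary", {
  map <- data.frame(snp = sprintf("s%02d", 1:40), chrom = "1",
                    pos = seq_len(40) * 100L)
  w <- defineWindows(map, 20)
  sigmaA2 <- 4
  # window 1 exactly at 0.5%, window 2 just below
  sv <- c(rep(0.00025 * sigmaA2, 20), rep(0.00024999 * sigmaA2, 20))
  wf <- windowVariances(w, sv, sigmaA2)
  expect_equal(wf$varPct[1], 0.5)
  sig <- significantWindows(wf, 0.5)
  expect_equal(sig$win, 1L)
  expect_equal(nrow(significantWindows(wf[0, ], 0.5)), 0L)
})

test_that("recurrence classes and UpSet counts match brute-force set algebra", {
  map <- data.frame(snp = sprintf("s%03d", 1:200), chrom = "1",
                    pos = seq_len(200) * 10L)
  grid <- defineWindows(map, 20)  # 10 windows
  set.seed(42)
  methods <- c("UM", "QM", "A_1.125", "A_1.2", "A_1.5")
  membership <- lapply(setNames(methods, methods), function(m)
    sort(sample(10, sample(2:6, 1))))
  perMethod <- lapply(membership, function(ix) {
    w <- grid[ix, , drop = FALSE]
    attr(w, "gridId") <- attr(grid, "gridId")
    w
  })
  res <- recurrenceClassify(perMethod)
  # brute force per window
  for (i in seq_len(nrow(res$recurrence))) {
    key <- res$recurrence$key[i]
    win <- grid$win[grid$key == key]
    detected <- names(membership)[vapply(membership, function(ix)
      win %in% ix, TRUE)]
    expect_setequal(strsplit(res$recurrence$methods[i], ",")[[1]], detected)
    n <- length(detected)
    expect_equal(res$recurrence$nMethods[i], n)
    expect_equal(res$recurrence$klass[i],
                 if (n >= 3) "stable" else if (n >= 2) "candidate_qtl"
                 else "singleton")
  }
  # UpSet counts = brute-force tally of identical method combinations
  combos <- table(vapply(seq_len(10), function(win) {
    det <- names(membership)[vapply(membership, function(ix)
      win %in% ix, TRUE)]
    paste(sort(det), collapse = ",")
  }, ""))
  combos <- combos[names(combos) != ""]
  expect_equal(sort(setNames(res$upset$count, res$upset$combination)),
               sort(unlist(as.list(combos))), ignore_attr = TRUE)

  # single-method input: everything is a singleton
  res1 <- recurrenceClassify(perMethod["UM"])
  expect_true(all(res1$recurrence$klass == "singleton"))

  # inconsistent grids across methods are rejected
  gridB <- defineWindows(map, 10)
  wb <- gridB[1:2, ]
  attr(wb, "gridId") <- attr(gridB, "gridId")
  expect_error(recurrenceClassify(list(UM = perMethod$UM, QM = wb)),
               "inconsistent window grids")
})

test_that("independent chromosome segment counts follow the Me formula", {
  expect_equal(round(effectiveChromosomeSegments(104, 30)), 1644)
  expect_equal(effectiveChromosomeSegments(5, 1), 10)  # log10(10) = 1
  # monotone increasing in Ne for fixed L
  grid <- vapply(seq(10, 500, by = 10), effectiveChromosomeSegments,
                 0, L = 30)
  expect_true(all(diff(grid) > 0))
  # natural-log variant stays available
  expect_equal(effectiveChromosomeSegments(5, 1, logBase = exp(1)),
               10 / log(10))
  expect_error(effectiveChromosomeSegments(-1, 30), "must be > 0")
})

test_that("gene annotation matches a brute-force interval scan", {
  set.seed(43)
  genes <- data.frame(
    chrom = sample(c("1", "2"), 50, replace = TRUE),
    start = sample.int(5e6, 50), geneId = sprintf("G%03d", 1:50),
    symbol = sprintf("SYM%03d", 1:50))
  genes$end <- genes$start + sample.int(2e5, 50)
  gtf <- writeToyGtf(genes)
  wins <- data.frame(key = c("1:1", "1:2", "2:1"),
                     chrom = c("1", "1", "2"),
                     bpStart = c(1e6, 3e6, 2e6),
                     bpEnd = c(1.2e6, 3.1e6, 2.4e6))
  ann <- annotateRegions(wins, gtf, flankBp = 500000L)
  # brute force O(n*m), closed intervals
  for (i in seq_len(nrow(wins))) {
    lo <- max(1, wins$bpStart[i] - 500000)
    hi <- wins$bpEnd[i] + 500000
    hitIds <- genes$geneId[genes$chrom == wins$chrom[i] &
                             genes$start <= hi & genes$end >= lo]
    expect_setequal(ann$geneId[ann$key == wins$key[i]], hitIds)
  }
  # overlap length equals the gene length for fully contained genes
  contained <- merge(ann, genes, by = "geneId")
  inside <- contained$start >= contained$regionStart &
    contained$end <= contained$regionEnd
  expect_equal(contained$overlapBp[inside],
               (contained$end - contained$start + 1)[inside])
})

test_that("a gene ending just before the flanked region is excluded", {
  genes <- data.frame(chrom = "1", start = 400000L, end = 499999L,
                      geneId = "G1", symbol = "S1")
  gtf <- writeToyGtf(genes)
  wins <- data.frame(key = "1:1", chrom = "1", bpStart = 1000000L,
                     bpEnd = 1100000L)
  # region starts at 500000; gene ends at 499999
  expect_equal(nrow(annotateRegions(wins, gtf, flankBp = 500000L)), 0L)
  genes2 <- transform(genes, end = 500000L)
  ann2 <- annotateRegions(wins, writeToyGtf(genes2), flankBp = 500000L)
  expect_equal(ann2$geneId, "G1")
  expect_equal(ann2$overlapBp, 1L)
})
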