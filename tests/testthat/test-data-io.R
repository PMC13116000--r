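test_that("pedigree construction sorts parents before offspring and round-trips", {
  # child listed first; parents must end up earlier
  ped <- Pedigree(c("C", "S", "D"), c("S", "0", "0"), c("D", "0", "0"))
  ids <- pedIds(ped)
  expect_lt(match("S", ids), match("C", ids))
  expect_lt(match("D", ids), match("C", ids))

  f <- tempfile(fileext = ".tsv")
  writePedigree(ped, f)
  ped2 <- readPedigree(f)
  expect_identical(as.data.frame(ped), as.data.frame(ped2))

  # single founder
  f2 <- tempfile(fileext = ".tsv")
  writeLines(c("animal\tsire\tdam", "A\t0\t0"), f2)
  expect_equal(pedIds(readPedigree(f2)), "A")
})

test_that("pedigree cycles, duplicates and phantom parents are handled", {
  expect_error(Pedigree(c("A", "B", "C"), c("B", "C", "A"),
                        c("0", "0", "0")), "cycle")
  expect_error(Pedigree(c("A", "A"), c("0", "0"), c("0", "0")),
               "duplicated")
  # a named but unlisted parent becomes a founder record
  ped <- Pedigree("kid", "papa", "mama")
  expect_setequal(pedIds(ped), c("kid", "papa", "mama"))
  expect_equal(sum(ped@sire == 0L & ped@dam == 0L), 2L)
})

test_that("genotype reading computes allele frequencies and round-trips", {
  dos <- matrix(c(0, 1, 2, 2, 2, 2), 3, 2,
                dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  map <- data.frame(snp = c("s1", "s2"), chrom = c("1", "1"),
                    pos = c(100L, 200L))
  g <- GenotypeMatrix(dos, map)
  expect_equal(alleleFreq(g), c(0.5, 1.0))

  gp <- tempfile(); mp <- tempfile()
  writeGenotypes(g, gp, mp)
  g2 <- readGenotypes(gp, mp)
  expect_equal(dosageMatrix(g2), dosageMatrix(g))
  expect_equal(snpMap(g2)$pos, snpMap(g)$pos)

  # BLUPF90 missing code 5 and NA both give NA
  writeLines(c("animal\ts1\ts2", "a\t5\tNA", "b\t1\t2"), gp)
  g3 <- readGenotypes(gp, mp)
  expect_true(all(is.na(dosageMatrix(g3)["a", ])))
})

test_that("invalid dosages and all-missing SNPs are caught", {
  map1 <- data.frame(snp = "s1", chrom = "1", pos = 1L)
  expect_error(GenotypeMatrix(matrix(3, 1, 1, dimnames = list("a", "s1")),
                              map1), "invalid dosage")
  expect_warning(
    GenotypeMatrix(matrix(NA_real_, 2, 1,
                          dimnames = list(c("a", "b"), "s1")), map1),
    "allele frequency undefined")
})

test_that("map is sorted by chromosome then position, X last", {
  dos <- matrix(c(0, 1, 2, 0, 1, 2), 2, 3,
                dimnames = list(c("a", "b"), c("sX", "s2", "s10")))
  map <- data.frame(snp = c("sX", "s2", "s10"), chrom = c("X", "2", "10"),
                    pos = c(5L, 10L, 1L))
  g <- GenotypeMatrix(dos, map)
  expect_equal(snpMap(g)$chrom, c("2", "10", "X"))
  expect_equal(colnames(dosageMatrix(g)), c("s2", "s10", "sX"))
  gr <- snpRanges(g)
  expect_s4_class(gr, "GRanges")
  expect_equal(length(gr), 3L)
})

test_that("qcFilter applies rules in order with exact bookkeeping", {
  # animal d: 1 of 2 SNPs called -> call rate 0.5 < 0.9 -> removed
  dos <- rbind(a = c(0, 2), b = c(1, 2), c = c(2, 2), d = c(0, NA))
  colnames(dos) <- c("s1", "s2")
  map <- data.frame(snp = c("s1", "s2"), chrom = "1", pos = c(1L, 2L))
  g <- GenotypeMatrix(dos, map)
  res <- qcFilter(g, ped = NULL)
  expect_equal(res$report@samplesRemoved[["call_rate"]], 1L)
  expect_false("d" %in% rownames(dosageMatrix(res$genotypes)))
  # s2 monomorphic among remaining
  expect_equal(res$report@snpsRemoved[["monomorphic"]], 1L)
  r <- res$report
  expect_equal(r@before[1] - sum(r@samplesRemoved), r@after[1])
  expect_equal(r@before[2] - sum(r@snpsRemoved), r@after[2])
})

test_that("MAF rule removes p = 0.04 SNPs after sample filtering", {
  set.seed(1)
  n <- 50
  dos <- cbind(rare = c(rep(1, 4), rep(0, n - 4)),      # p = 0.04
               common = rbinom(n, 2, 0.4))
  rownames(dos) <- sprintf("a%02d", seq_len(n))
  map <- data.frame(snp = c("rare", "common"), chrom = "1", pos = c(1L, 2L))
  res <- qcFilter(GenotypeMatrix(dos, map), ped = NULL, mafMin = 0.05)
  expect_equal(res$report@snpsRemoved[["maf"]], 1L)
  expect_equal(snpMap(res$genotypes)$snp, "common")
})

test_that("opposing-homozygote conflicts remove the SNP", {
  ped <- trioPed()
  # s1: parent S = 0, child C = 2 -> impossible; s2 clean
  dos <- rbind(S = c(0, 1), D = c(1, 1), C = c(2, 1))
  colnames(dos) <- c("s1", "s2")
  map <- data.frame(snp = c("s1", "s2"), chrom = "1", pos = c(1L, 2L))
  # disable sample-level removal to isolate the SNP rule
  res <- qcFilter(GenotypeMatrix(dos, map), ped, mafMin = 1e-9,
                  mendelSampleRate = 1)
  expect_equal(res$report@snpsRemoved[["mendelian"]], 1L)
  expect_equal(snpMap(res$genotypes)$snp, "s2")
})

test_that("qcFilter is idempotent and errors on an empty panel", {
  set.seed(4)
  n <- 60; m <- 40
  dos <- matrix(rbinom(n * m, 2, rep(runif(m, 0.1, 0.9), each = n)), n, m)
  dos[runif(n * m) < 0.02] <- NA
  rownames(dos) <- sprintf("a%02d", seq_len(n))
  colnames(dos) <- sprintf("s%02d", seq_len(m))
  map <- data.frame(snp = colnames(dos), chrom = "1",
                    pos = seq_len(m) * 10L)
  res1 <- qcFilter(GenotypeMatrix(dos, map), ped = NULL)
  res2 <- qcFilter(res1$genotypes, ped = NULL)
  expect_equal(sum(res2$report@samplesRemoved), 0L)
  expect_equal(sum(res2$report@snpsRemoved), 0L)

  mono <- matrix(2, 3, 1, dimnames = list(c("a", "b", "c"), "s1"))
  expect_error(qcFilter(GenotypeMatrix(mono,
                                       data.frame(snp = "s1", chrom = "1",
                                                  pos = 1L)), NULL),
               "empty panel")
})

test_that("contemporary-group filtering drops small groups, keeps sane outliers", {
  ph <- data.frame(
    animal = sprintf("a%d", 1:9),
    trait = c(10, 10, 10, 10, 100, 5, 6, 1, 1),
    cg = c(rep("big", 5), rep("tiny", 2), rep("dup", 2)),
    age = 500L)
  res <- buildContemporaryGroups(ph, minGroupSize = 3, outlierSd = 3)
  # tiny (2 records) and dup (2 records) removed entirely
  expect_false(any(res$phenotypes$cg %in% c("tiny", "dup")))
  expect_equal(sum(res$log$reason == "small_group"), 4L)
  # |100 - 28| = 72 < 3 * 40.25 -> retained
  expect_true(100 %in% res$phenotypes$trait)

  # zero-variance group untouched
  ph2 <- data.frame(animal = sprintf("b%d", 1:5), trait = 7, cg = "z",
                    age = 1L)
  expect_equal(nrow(buildContemporaryGroups(ph2)$phenotypes), 5L)

  # a genuine outlier is removed in a single pass
  ph3 <- data.frame(animal = sprintf("c%d", 1:20),
                    trait = c(rnorm(19, 0, 0.1), 50), cg = "w", age = 1L)
  res3 <- buildContemporaryGroups(ph3)
  expect_equal(res3$log$reason, "outlier")
  expect_equal(nrow(res3$phenotypes), 19L)

  expect_error(buildContemporaryGroups(ph[6:7, ]), "no phenotype records")
})
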