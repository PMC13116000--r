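# Chromosome ordering: numeric labels first in numeric order, then X, then
# anything else alphabetically. Used everywhere a map must be sorted.
chromRank <- function(chrom) {
  ch <- as.character(chrom)
  num <- suppressWarnings(as.numeric(ch))
  r <- ifelse(!is.na(num), num,
              ifelse(ch == "X", 1e6,
                     1e6 + 1 + as.numeric(factor(ch))))
  r
}

# sum(2 p q) over SNPs; the VanRaden scaling constant.
sumTwoPq <- function(p) {
  sum(2 * p * (1 - p))
}

readTsv <- function(path, ...) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

writeTsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
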