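#' Partition the SNP map into windows of adjacent SNPs
#'
#' Per chromosome, consecutive non-overlapping blocks of `windowSize`
#' physically ordered SNPs; a trailing block keeps its remaining (< 20)
#' SNPs and is flagged in `full = FALSE`. Window boundaries never cross
#' chromosomes.
#'
#' @param map SNP map data.frame (`snp`, `chrom`, `pos`), sorted by
#'   (chrom, pos).
#' @param windowSize SNPs per window (default 20).
#' @return data.frame with columns `key`, `chrom`, `win` (1-based within
#'   chromosome), `snpStart`, `snpEnd` (row indices into `map`),
#'   `bpStart`, `bpEnd`, `nSnps`, `full`; attribute `"gridId"` identifies
#'   the grid for recurrence matching.
#' @export
defineWindows <- function(map, windowSize = 20L) {
  if (!nrow(map)) stop("empty SNP map")
  ord <- order(chromRank(map$chrom), map$pos)
  if (!identical(ord, seq_len(nrow(map))))
    stop("map must be sorted by (chrom, pos)")
  out <- do.call(rbind, lapply(split(seq_len(nrow(map)),
                                     factor(map$chrom,
                                            unique(map$chrom))), function(ix) {
    nw <- ceiling(length(ix) / windowSize)
    win <- rep(seq_len(nw), each = windowSize)[seq_along(ix)]
    first <- ix[!duplicated(win)]
    last <- ix[!duplicated(win, fromLast = TRUE)]
    data.frame(chrom = map$chrom[first], win = seq_len(nw),
               snpStart = first, snpEnd = last,
               bpStart = map$pos[first], bpEnd = map$pos[last],
               nSnps = as.integer(table(win)), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out$full <- out$nSnps == windowSize
  out <- cbind(key = paste0(out$chrom, ":", out$win), out)
  out$key <- as.character(out$key)
  attr(out, "gridId") <- paste(out$chrom, out$snpStart, out$snpEnd,
                               collapse = ";")
  out
}

#' Window additive-genetic-variance shares
#'
#' Fills each window with the sum of its member SNP variances (`varAbs`)
#' and the percentage of additive genetic variance it explains
#' (`varPct = 100 * varAbs / sigmaA2`).
#'
#' @param windows output of [defineWindows()].
#' @param snpVar per-SNP variances aligned to the map used to define the
#'   windows.
#' @param sigmaA2 additive genetic variance (> 0).
#' @return `windows` with `varAbs` and `varPct` columns.
#' @export
windowVariances <- function(windows, snpVar, sigmaA2) {
  if (sigmaA2 <= 0) stop("sigmaA2 must be > 0")
  if (max(windows$snpEnd) > length(snpVar))
    stop("snpVar shorter than the window grid")
  grid <- attr(windows, "gridId")
  windows$varAbs <- vapply(seq_len(nrow(windows)), function(i)
    sum(snpVar[windows$snpStart[i]:windows$snpEnd[i]]), 0)
  windows$varPct <- 100 * windows$varAbs / sigmaA2
  attr(windows, "gridId") <- grid
  windows
}

#' Windows above the variance threshold
#'
#' Keeps windows explaining at least `thresholdPct` percent of the
#' additive genetic variance (ties at the threshold included).
#'
#' @param windows output of [windowVariances()].
#' @param thresholdPct threshold in percent (default 0.5).
#' @return filtered data.frame (grid attribute preserved).
#' @export
significantWindows <- function(windows, thresholdPct = 0.5) {
  grid <- attr(windows, "gridId")
  out <- windows[windows$varPct >= thresholdPct, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "gridId") <- grid
  out
}

#' Classify window recurrence across analytical approaches
#'
#' Exact-key matching of significant windows on a shared window grid.
#' Windows detected by at least two approaches are candidate QTL regions;
#' by at least three, stable; by one, singletons. Also tabulates
#' UpSet-style intersection counts per method combination.
#'
#' @param perMethod named list of significant-window data.frames (from
#'   [significantWindows()]), one per approach, all on the same grid.
#' @return list with `recurrence` (data.frame: key, chrom, win, snpStart,
#'   snpEnd, methods, nMethods, klass) and `upset` (data.frame:
#'   combination, count).
#' @export
recurrenceClassify <- function(perMethod) {
  stopifnot(is.list(perMethod), length(perMethod) >= 1,
            !is.null(names(perMethod)))
  grids <- unique(vapply(perMethod, function(w) {
    g <- attr(w, "gridId")
    if (is.null(g)) NA_character_ else g
  }, ""))
  grids <- grids[!is.na(grids)]
  if (length(grids) > 1)
    stop("inconsistent window grids across methods")
  allw <- do.call(rbind, lapply(names(perMethod), function(mm) {
    w <- perMethod[[mm]]
    if (!nrow(w)) return(NULL)
    cbind(w[, c("key", "chrom", "win", "snpStart", "snpEnd")], method = mm)
  }))
  if (is.null(allw))
    return(list(recurrence = data.frame(), upset = data.frame()))
  sp <- split(allw$method, allw$key)
  keys <- names(sp)
  first <- allw[!duplicated(allw$key), ]
  first <- first[match(keys, first$key), ]
  nm <- lengths(sp)
  rec <- data.frame(
    key = keys, chrom = first$chrom, win = first$win,
    snpStart = first$snpStart, snpEnd = first$snpEnd,
    methods = vapply(sp, function(x) paste(sort(unique(x)),
                                           collapse = ","), ""),
    nMethods = as.integer(nm),
    klass = ifelse(nm >= 3, "stable",
                   ifelse(nm >= 2, "candidate_qtl", "singleton")),
    stringsAsFactors = FALSE)
  rec <- rec[order(chromRank(rec$chrom), rec$win), ]
  rownames(rec) <- NULL
  up <- as.data.frame(table(rec$methods), stringsAsFactors = FALSE)
  names(up) <- c("combination", "count")
  list(recurrence = rec, upset = up)
}

#' Expected number of independent chromosome segments
#'
#' `Me = 2 Ne L / log(2 Ne L)`, the effective number of independently
#' segregating genome segments for effective population size `Ne` and
#' total map length `L` (Morgans). The base-10 logarithm is the default;
#' set `logBase = exp(1)` for the natural-log form of the source
#' literature.
#'
#' @param Ne effective population size (> 0).
#' @param L map length in Morgans (> 0).
#' @param logBase logarithm base (default 10).
#' @return the expected segment count (not rounded).
#' @examples
#' effectiveChromosomeSegments(104, 30)  # about 1644
#' @export
effectiveChromosomeSegments <- function(Ne, L, logBase = 10) {
  if (Ne <= 0 || L <= 0) stop("Ne and L must be > 0")
  x <- 2 * Ne * L
  if (x <= 1) stop("2 * Ne * L must exceed 1")
  x / log(x, base = logBase)
}

#' Manhattan-style window plot
#'
#' Plots window variance percentages against genome position, one point
#' per window, with the detection threshold drawn as a horizontal line.
#'
#' @param windows output of [windowVariances()].
#' @param thresholdPct threshold line (default 0.5).
#' @param main plot title.
#' @return invisibly, the plotted data.frame (chrom, midpoint bp, varPct).
#' @export
plotManhattan <- function(windows, thresholdPct = 0.5, main = "") {
  chroms <- unique(windows$chrom)
  off <- setNames(cumsum(c(0, vapply(chroms, function(c)
    max(windows$bpEnd[windows$chrom == c]), 0)))[seq_along(chroms)], chroms)
  mid <- (windows$bpStart + windows$bpEnd) / 2
  x <- mid + off[windows$chrom]
  col <- (match(windows$chrom, chroms) %% 2) + 1
  graphics::plot(x, windows$varPct, pch = 16, cex = 0.6,
                 col = c("grey40", "steelblue")[col],
                 xlab = "genome position", ylab = "% additive variance",
                 main = main)
  graphics::abline(h = thresholdPct, col = "red")
  invisible(data.frame(chrom = windows$chrom, midpointBp = mid,
                       varPct = windows$varPct))
}
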