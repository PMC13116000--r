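#' Annotate flanked window regions with genes from a GTF
#'
#' Each window is extended by `flankBp` up- and downstream (clipped at
#' position 1) and intersected with the gene features of an Ensembl-style
#' GTF (1-based, inclusive coordinates). Genes are reported once per
#' region with the length of their overlap.
#'
#' @param windows window data.frame (needs `key`, `chrom`, `bpStart`,
#'   `bpEnd`), e.g. the recurrent windows.
#' @param gtf path to a GTF file, or a `GRanges` of gene features with a
#'   `gene_id` metadata column.
#' @param flankBp flank size in bp (default 500000).
#' @return data.frame (key, chrom, regionStart, regionEnd, geneId, symbol,
#'   overlapBp); zero rows when nothing overlaps.
#' @export
annotateRegions <- function(windows, gtf, flankBp = 500000L) {
  genes <- if (is(gtf, "GRanges")) gtf else readGtfGenes(gtf)
  if (!nrow(windows))
    return(data.frame(key = character(0), chrom = character(0),
                      regionStart = integer(0), regionEnd = integer(0),
                      geneId = character(0), symbol = character(0),
                      overlapBp = integer(0)))
  regions <- GenomicRanges::GRanges(
    seqnames = as.character(windows$chrom),
    ranges = IRanges::IRanges(start = pmax(1L, windows$bpStart - flankBp),
                              end = windows$bpEnd + flankBp),
    key = windows$key)
  hits <- GenomicRanges::findOverlaps(regions, genes)
  if (!length(hits))
    return(annotateRegions(windows[0, , drop = FALSE], genes, flankBp))
  ri <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::pintersect(regions[ri], genes[gi])
  sym <- if ("gene_name" %in% names(S4Vectors::mcols(genes)))
    S4Vectors::mcols(genes)$gene_name[gi]
  else S4Vectors::mcols(genes)$gene_id[gi]
  sym[is.na(sym)] <- S4Vectors::mcols(genes)$gene_id[gi][is.na(sym)]
  out <- data.frame(
    key = S4Vectors::mcols(regions)$key[ri],
    chrom = as.character(GenomicRanges::seqnames(regions))[ri],
    regionStart = GenomicRanges::start(regions)[ri],
    regionEnd = GenomicRanges::end(regions)[ri],
    geneId = S4Vectors::mcols(genes)$gene_id[gi],
    symbol = sym,
    overlapBp = GenomicRanges::width(ov),
    stringsAsFactors = FALSE)
  out <- out[!duplicated(paste(out$key, out$geneId)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read gene features from a GTF file
#'
#' Imports a GTF with `rtracklayer` and keeps `gene` features (falling
#' back to the span of each `gene_id`'s features for GTFs without explicit
#' gene rows).
#'
#' @param path GTF path.
#' @return a `GRanges` with `gene_id` (and `gene_name` when present).
#' @export
readGtfGenes <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  if ("type" %in% names(S4Vectors::mcols(gr)) &&
      any(gr$type == "gene")) {
    gr <- gr[gr$type == "gene"]
  } else {
    spl <- GenomicRanges::split(gr, gr$gene_id)
    rng <- unlist(range(spl))
    S4Vectors::mcols(rng)$gene_id <- names(rng)
    gr <- rng
  }
  if (is.null(gr$gene_id)) stop("GTF lacks gene_id attributes")
  gr
}
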