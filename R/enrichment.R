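#' Read gene sets from a GMT file
#'
#' @param path GMT path (one set per line: id, description, genes...).
#' @return named list of character vectors.
#' @export
readGmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test of a gene list against each gene set,
#' restricted to a gene universe, with Benjamini-Hochberg adjustment
#' across terms. Terms without any list gene are reported with p = 1.
#'
#' @param geneList character vector of genes of interest (must lie within
#'   the universe).
#' @param geneSets named list of character vectors (e.g. [readGmt()]).
#' @param universe character vector of background genes.
#' @return data.frame (termId, termName, k, K, n, N, pValue, pAdjusted),
#'   ordered by p-value. `k` = list genes in the set, `K` = set size in
#'   the universe, `n` = list size, `N` = universe size.
#' @export
hypergeometricEnrichment <- function(geneList, geneSets, universe) {
  universe <- unique(as.character(universe))
  N <- length(universe)
  if (!N) stop("empty gene universe")
  geneList <- unique(as.character(geneList))
  outside <- setdiff(geneList, universe)
  if (length(outside))
    stop("gene list contains genes outside the universe: ",
         paste(head(outside), collapse = ", "))
  n <- length(geneList)
  res <- lapply(names(geneSets), function(term) {
    set <- intersect(unique(geneSets[[term]]), universe)
    K <- length(set)
    k <- length(intersect(geneList, set))
    p <- if (k == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(termId = term, termName = term, k = k, K = K, n = n, N = N,
               pValue = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$pAdjusted <- p.adjust(out$pValue, method = "BH")
  out <- out[order(out$pValue, out$termId), ]
  rownames(out) <- NULL
  out
}

#' Term recurrence across analytical approaches
#'
#' Builds a term-by-method incidence table from per-method enrichment
#' results (or plain term vectors) and counts in how many approaches each
#' term appears — supporting "detected by at least three approaches"
#' style filtering.
#'
#' @param perMethod named list; each element either an enrichment
#'   data.frame with a `termId` column or a character vector of term ids.
#' @param pMax optional p-value cutoff applied to data.frames (on
#'   `pAdjusted`); default `NULL` keeps every reported term.
#' @return list with `incidence` (logical matrix, terms x methods) and
#'   `counts` (data.frame: termId, nMethods, methods).
#' @export
compareAcrossMethods <- function(perMethod, pMax = NULL) {
  stopifnot(is.list(perMethod), !is.null(names(perMethod)))
  termsOf <- function(x) {
    if (is.character(x)) return(unique(x))
    if (!is.null(pMax)) x <- x[x$pAdjusted <= pMax, , drop = FALSE]
    unique(x$termId)
  }
  lists <- lapply(perMethod, termsOf)
  allTerms <- sort(unique(unlist(lists)))
  inc <- vapply(lists, function(tt) allTerms %in% tt,
                logical(length(allTerms)))
  if (length(allTerms) == 1L) inc <- matrix(inc, nrow = 1L,
                                            dimnames = list(allTerms,
                                                            names(perMethod)))
  else rownames(inc) <- allTerms
  counts <- data.frame(
    termId = allTerms,
    nMethods = as.integer(rowSums(inc)),
    methods = apply(inc, 1, function(r)
      paste(colnames(inc)[r], collapse = ",")),
    stringsAsFactors = FALSE)
  rownames(counts) <- NULL
  list(incidence = inc, counts = counts)
}
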