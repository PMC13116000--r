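#' Construct a Pedigree
#'
#' Builds a [Pedigree-class] from animal/sire/dam triples. Records are
#' topologically sorted so that every parent precedes its offspring; the
#' original ids are preserved. Parents that are named but never listed as
#' animals are added as founders. Cycles (an animal among its own
#' ancestors) and duplicated ids are errors.
#'
#' @param animal,sire,dam character vectors; `"0"`, `""` or `NA` denote an
#'   unknown parent.
#' @return a [Pedigree-class].
#' @examples
#' ped <- Pedigree(c("C", "S", "D"), c("S", "0", "0"), c("D", "0", "0"))
#' pedIds(ped)  # parents reordered before the child
#' @export
Pedigree <- function(animal, sire, dam) {
  animal <- as.character(animal)
  sire <- as.character(sire)
  dam <- as.character(dam)
  unk <- function(x) is.na(x) | x == "0" | x == ""
  sire[unk(sire)] <- NA_character_
  dam[unk(dam)] <- NA_character_
  if (anyDuplicated(animal))
    stop("duplicated animal id: ", animal[duplicated(animal)][1])
  phantom <- setdiff(c(sire, dam), c(animal, NA_character_))
  if (length(phantom)) {
    animal <- c(phantom, animal)
    sire <- c(rep(NA_character_, length(phantom)), sire)
    dam <- c(rep(NA_character_, length(phantom)), dam)
  }
  n <- length(animal)
  si <- match(sire, animal)
  di <- match(dam, animal)
  # Kahn topological sort on the parent -> offspring DAG
  indeg <- (!is.na(si)) + (!is.na(di))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i]))
      if (!is.na(p)) children[[p]] <- c(children[[p]], i)
  }
  order_out <- integer(0)
  queue <- which(indeg == 0L)
  indeg_w <- indeg
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    order_out <- c(order_out, v)
    for (ch in children[[v]]) {
      indeg_w[ch] <- indeg_w[ch] - 1L
      if (indeg_w[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order_out) < n) {
    bad <- animal[setdiff(seq_len(n), order_out)][1]
    stop("pedigree cycle detected involving animal '", bad, "'")
  }
  pos <- match(seq_len(n), order_out)  # old index -> new position
  id_new <- animal[order_out]
  si_new <- ifelse(is.na(si[order_out]), 0L, pos[si[order_out]])
  di_new <- ifelse(is.na(di[order_out]), 0L, pos[di[order_out]])
  new("Pedigree", id = id_new, sire = as.integer(si_new),
      dam = as.integer(di_new))
}

#' Read a pedigree file
#'
#' Reads a 3-column TSV (animal, sire, dam; header optional; `"0"` codes an
#' unknown parent) and returns a topologically ordered [Pedigree-class].
#'
#' @param path path to the TSV file.
#' @return a [Pedigree-class].
#' @export
readPedigree <- function(path) {
  first <- strsplit(readLines(path, n = 1L), "\t")[[1]]
  has_header <- identical(tolower(first[1]), "animal")
  df <- read.table(path, header = has_header, sep = "\t",
                   colClasses = "character")
  if (ncol(df) < 3) stop("pedigree file must have 3 columns")
  Pedigree(df[[1]], df[[2]], df[[3]])
}

#' Write a pedigree file
#'
#' @param ped a [Pedigree-class].
#' @param path output path (TSV with header; unknown parents as `"0"`).
#' @export
writePedigree <- function(ped, path) {
  writeTsv(as.data.frame(ped), path)
}

#' @export
#' @describeIn Pedigree data.frame view (animal, sire, dam; `"0"` unknown).
#' @param x a [Pedigree-class].
#' @param ... ignored.
as.data.frame.Pedigree <- function(x, ...) {
  data.frame(animal = x@id,
             sire = ifelse(x@sire == 0L, "0", x@id[pmax(x@sire, 1L)]),
             dam = ifelse(x@dam == 0L, "0", x@id[pmax(x@dam, 1L)]),
             stringsAsFactors = FALSE)
}
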