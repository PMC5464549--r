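#' Collapse an alignment to a haplotype-by-location count table
#'
#' Sequences that are exactly identical (after uppercasing) share one
#' haplotype; no ambiguity resolution is attempted, so sequences containing
#' N collapse only with identical strings. Haplotypes are ordered by
#' decreasing total count, ties broken by sequence lexicographic order, and
#' labelled H001, H002, ...
#'
#' @param aln a \linkS4class{HaploAlignment}.
#' @return a \linkS4class{HaplotypeTable}.
#' @examples
#' aln <- HaploAlignment(
#'   c(a = "AAAA", b = "AAAA", c = "AAAT"),
#'   data.frame(sample_id = c("a", "b", "c"), location = "L", area = "A"))
#' collapseHaplotypes(aln)
#' @export
collapseHaplotypes <- function(aln) {
  stopifnot(is(aln, "HaploAlignment"))
  if (length(aln) == 0L) stop("empty-input error: no sequences")
  sq <- as.character(aln@seqs)
  loc <- as.character(aln@meta$location)
  area <- as.character(aln@meta$area)
  uniq <- sort(unique(sq))
  counts <- table(factor(sq, levels = uniq), factor(loc))
  counts <- matrix(as.integer(counts), nrow = length(uniq),
                   dimnames = dimnames(counts))
  ord <- order(-rowSums(counts), uniq)
  counts <- counts[ord, , drop = FALSE]
  uniq <- uniq[ord]
  ids <- sprintf("H%03d", seq_along(uniq))
  rownames(counts) <- ids
  haps <- Biostrings::DNAStringSet(uniq)
  names(haps) <- ids
  areas <- vapply(colnames(counts),
                  function(l) area[match(l, loc)], character(1))
  new("HaplotypeTable", hapSeqs = haps, counts = counts, areas = areas)
}

#' Expand a haplotype count table to individual-level data
#'
#' Emits one sequence record per counted individual, with synthetic sample
#' ids; \code{collapseHaplotypes(expandFromCounts(ht))} reproduces the table
#' up to row/column order.
#'
#' @param ht a \linkS4class{HaplotypeTable}.
#' @return a \linkS4class{HaploAlignment}.
#' @export
expandFromCounts <- function(ht) {
  stopifnot(is(ht, "HaplotypeTable"))
  cm <- ht@counts
  if (any(cm < 0)) stop("validation error: negative count")
  if (sum(cm) == 0L) stop("empty-input error: all counts are zero")
  sq <- as.character(ht@hapSeqs)
  recs <- character(0); locs <- character(0)
  for (j in seq_len(ncol(cm))) {
    reps <- rep.int(seq_len(nrow(cm)), cm[, j])
    recs <- c(recs, sq[reps])
    locs <- c(locs, rep(colnames(cm)[j], length(reps)))
  }
  ids <- sprintf("S%04d", seq_along(recs))
  names(recs) <- ids
  meta <- data.frame(sample_id = ids, location = locs,
                     area = unname(ht@areas[locs]),
                     stringsAsFactors = FALSE)
  HaploAlignment(recs, meta)
}

#' Read/write a haplotype count table
#'
#' TSV format: first column \code{sequence} (the haplotype sequence),
#' remaining columns per-location counts; a companion header line
#' \code{# area: <location>=<area> ...} records the location-to-area map.
#'
#' @param ht a \linkS4class{HaplotypeTable}
#' @param path output path
#' @return \code{writeHaplotypeTable}: the path, invisibly;
#'   \code{readHaplotypeTable}: a \linkS4class{HaplotypeTable}.
#' @export
writeHaplotypeTable <- function(ht, path) {
  hdr <- paste0("# area: ", paste(names(ht@areas), ht@areas,
                                  sep = "=", collapse = " "))
  df <- data.frame(sequence = as.character(ht@hapSeqs),
                   ht@counts, check.names = FALSE)
  con <- file(path, "w")
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname writeHaplotypeTable
#' @export
readHaplotypeTable <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "# area:"))
    stop("missing '# area:' header line")
  pairs <- strsplit(trimws(sub("^# area:", "", first)), " ")[[1]]
  kv <- strsplit(pairs, "=", fixed = TRUE)
  areas <- vapply(kv, `[`, character(1), 2)
  names(areas) <- vapply(kv, `[`, character(1), 1)
  df <- utils::read.delim(path, skip = 1L, check.names = FALSE,
                          stringsAsFactors = FALSE)
  cm <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(cm) <- "integer"
  ids <- sprintf("H%03d", seq_len(nrow(df)))
  rownames(cm) <- ids
  haps <- Biostrings::DNAStringSet(toupper(df$sequence))
  names(haps) <- ids
  new("HaplotypeTable", hapSeqs = haps, counts = cm, areas = areas)
}

#' @rdname HaplotypeTable-class
#' @export
setMethod("hapCounts", "HaplotypeTable", function(x) x@counts)

#' @rdname HaplotypeTable-class
#' @export
setMethod("hapSequences", "HaplotypeTable", function(x) x@hapSeqs)

#' @rdname HaplotypeTable-class
#' @export
setMethod("nHaplotypes", "HaplotypeTable",
          function(x) length(x@hapSeqs))

#' @rdname HaplotypeTable-class
#' @export
setMethod("nPolymorphic", "HaplotypeTable",
          function(x) .nPolySites(.encodeSeqs(x@hapSeqs)))

#' @rdname HaplotypeTable-class
#' @export
setMethod("areaMap", "HaplotypeTable", function(x) x@areas)

#' Number of singleton haplotypes (total count 1)
#' @param ht a \linkS4class{HaplotypeTable}
#' @export
nSingletons <- function(ht) sum(rowSums(ht@counts) == 1L)

#' @rdname HaplotypeTable-class
#' @param object a HaplotypeTable
#' @export
setMethod("show", "HaplotypeTable", function(object) {
  cat("HaplotypeTable:", nHaplotypes(object), "haplotypes,",
      sum(object@counts), "individuals,",
      ncol(object@counts), "locations\n")
  cat("  polymorphic sites:", nPolymorphic(object),
      " singletons:", nSingletons(object), "\n")
})
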