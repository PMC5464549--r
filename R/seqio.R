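#' Construct a HaploAlignment
#'
#' @param seqs a \link[Biostrings]{DNAStringSet} or named character vector of
#'   aligned sequences (identical lengths; alphabet A, C, G, T, N, -).
#' @param meta a data.frame or DataFrame with columns \code{sample_id},
#'   \code{location}, \code{area} and optional \code{lat}, \code{lon}.
#'   Rows are matched to sequences by \code{sample_id}.
#' @return a \linkS4class{HaploAlignment}.
#' @examples
#' aln <- HaploAlignment(
#'   c(s1 = "ACGT", s2 = "ACGA"),
#'   data.frame(sample_id = c("s1", "s2"), location = "L1", area = "A1"))
#' sequences(aln)
#' @export
HaploAlignment <- function(seqs, meta) {
  if (!is(seqs, "DNAStringSet")) {
    nm <- names(seqs)
    seqs <- toupper(as.character(seqs))
    if (length(unique(nchar(seqs))) > 1L)
      stop("alignment error: sequences differ in length")
    seqs <- Biostrings::DNAStringSet(seqs)
    names(seqs) <- nm
  }
  meta <- as.data.frame(meta)
  if (!all(c("sample_id", "location", "area") %in% colnames(meta)))
    stop("metadata error: need columns sample_id, location, area")
  missing <- setdiff(names(seqs), as.character(meta$sample_id))
  if (length(missing))
    stop("metadata error: samples absent from metadata: ",
         paste(utils::head(missing, 5), collapse = ", "))
  meta <- meta[match(names(seqs), as.character(meta$sample_id)), , drop = FALSE]
  rownames(meta) <- NULL
  for (col in c("sample_id", "location", "area"))
    meta[[col]] <- as.character(meta[[col]])
  new("HaploAlignment", seqs = seqs, meta = S4Vectors::DataFrame(meta))
}

#' Read an alignment and its sample metadata
#'
#' Reads a FASTA alignment (wrapped or unwrapped) and a tab-separated
#' metadata table with header \code{sample_id location area lat lon}
#' (\code{lat}/\code{lon} optional), validates both, and returns them with
#' metadata rows ordered as in the FASTA.
#'
#' @param fastaPath path to the FASTA file.
#' @param metadataPath path to the TSV metadata file.
#' @return a \linkS4class{HaploAlignment}.
#' @export
readAlignment <- function(fastaPath, metadataPath) {
  if (!file.exists(fastaPath)) stop("FASTA file not found: ", fastaPath)
  if (!file.exists(metadataPath))
    stop("metadata file not found: ", metadataPath)
  seqs <- Biostrings::readDNAStringSet(fastaPath)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (length(unique(Biostrings::width(seqs))) > 1L)
    stop("alignment error: sequences differ in length")
  bad <- .illegalLetters(seqs)
  if (length(bad))
    stop("alphabet error: illegal characters ", paste(bad, collapse = ", "))
  meta <- utils::read.delim(metadataPath, stringsAsFactors = FALSE)
  HaploAlignment(seqs, meta)
}

#' Write an alignment and its metadata
#'
#' @param aln a \linkS4class{HaploAlignment}.
#' @param fastaPath,metadataPath output paths.
#' @return invisibly, the two paths.
#' @export
writeAlignment <- function(aln, fastaPath, metadataPath) {
  Biostrings::writeXStringSet(sequences(aln), fastaPath)
  utils::write.table(as.data.frame(sampleInfo(aln)), metadataPath,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fastaPath, metadataPath))
}

#' @rdname HaploAlignment-class
#' @export
setMethod("sequences", "HaploAlignment", function(x) x@seqs)

#' @rdname HaploAlignment-class
#' @export
setMethod("sampleInfo", "HaploAlignment", function(x) x@meta)

#' @rdname HaploAlignment-class
#' @param object a HaploAlignment
#' @export
setMethod("show", "HaploAlignment", function(object) {
  cat("HaploAlignment:", length(object@seqs), "sequences x",
      Biostrings::width(object@seqs)[1L], "bp\n")
  cat("  locations:", length(unique(object@meta$location)),
      " areas:", length(unique(object@meta$area)), "\n")
})

#' @rdname HaploAlignment-class
#' @export
setMethod("length", "HaploAlignment", function(x) length(x@seqs))

#' Subset a HaploAlignment by sample
#'
#' @param x a \linkS4class{HaploAlignment}
#' @param i index, logical or sample-id vector
#' @param j,drop,... ignored
#' @export
setMethod("[", "HaploAlignment", function(x, i, j, ..., drop = FALSE) {
  new("HaploAlignment", seqs = x@seqs[i], meta = x@meta[i, , drop = FALSE])
})

#' Pairwise nucleotide differences
#'
#' Counts, for every unordered pair of sequences, the number of aligned sites
#' at which both sequences carry an unambiguous base (A/C/G/T) and the bases
#' differ. Sites with N or a gap in either member of a pair are excluded from
#' that pair's comparison (pairwise deletion).
#'
#' @param aln a \linkS4class{HaploAlignment}, DNAStringSet or character
#'   vector of aligned sequences.
#' @return a symmetric integer matrix of difference counts with a
#'   \code{"shared"} attribute holding the per-pair number of compared sites.
#' @export
pairwiseDifferences <- function(aln) {
  enc <- if (is(aln, "HaploAlignment")) .encodeSeqs(aln@seqs)
         else .encodeSeqs(aln)
  .pairDiff(enc)
}

# core: diff counts and shared (both-unambiguous) site counts via
# indicator cross-products
.pairDiff <- function(enc) {
  valid <- (enc > 0L) * 1
  shared <- tcrossprod(valid)
  same <- matrix(0, nrow(enc), nrow(enc))
  for (b in 1:4) same <- same + tcrossprod((enc == b) * 1)
  d <- shared - same
  storage.mode(d) <- "integer"
  dimnames(d) <- list(rownames(enc), rownames(enc))
  dimnames(shared) <- dimnames(d)
  attr(d, "shared") <- shared
  d
}

# number of polymorphic sites: sites with >= 2 distinct unambiguous states
.nPolySites <- function(enc) {
  if (nrow(enc) == 0L) return(0L)
  states <- vapply(1:4, function(b) colSums(enc == b) > 0L,
                   logical(ncol(enc)))
  if (is.null(dim(states))) states <- matrix(states, nrow = 1L)
  sum(rowSums(states) >= 2L)
}

#' Great-circle distances between locations
#'
#' Haversine great-circle distance in kilometres between location
#' coordinates, as a fallback when over-water (nautical) distances are not
#' available. Results are labelled as great-circle in the attribute
#' \code{"method"}.
#'
#' @param meta a data.frame/DataFrame with columns \code{location},
#'   \code{lat}, \code{lon} (one row per sample or per location).
#' @return symmetric matrix of distances (km) between unique locations.
#' @export
greatCircleDistances <- function(meta) {
  meta <- as.data.frame(meta)
  if (!all(c("location", "lat", "lon") %in% colnames(meta)))
    stop("need columns location, lat, lon")
  u <- meta[!duplicated(meta$location), c("location", "lat", "lon")]
  if (anyNA(u$lat) || anyNA(u$lon))
    stop("missing coordinates for some locations")
  m <- geosphere::distm(cbind(u$lon, u$lat),
                        fun = geosphere::distHaversine) / 1000
  dimnames(m) <- list(u$location, u$location)
  attr(m, "method") <- "great-circle"
  m
}
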