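#' Haplotype (gene) diversity with Nei's sampling variance
#'
#' Nei's (1987) unbiased estimator h = n/(n-1) (1 - sum p_i^2) with the
#' standard deviation from his sampling variance,
#' V(h) = 2/(n(n-1)) { 2(n-2)[sum p^3 - (sum p^2)^2] + sum p^2 - (sum p^2)^2 }.
#'
#' @param freqs positive integer haplotype counts.
#' @return list with elements \code{h} and \code{sd}.
#' @examples
#' haplotypeDiversity(c(10, 5, 5, 4))
#' @export
haplotypeDiversity <- function(freqs) {
  freqs <- freqs[freqs > 0]
  n <- sum(freqs)
  if (n < 2) stop("insufficient-sample error: need n >= 2")
  p <- freqs / n
  s2 <- sum(p^2); s3 <- sum(p^3)
  h <- n / (n - 1) * (1 - s2)
  v <- 2 / (n * (n - 1)) *
    (2 * (n - 2) * (s3 - s2^2) + s2 - s2^2)
  list(h = h, sd = sqrt(max(v, 0)))
}

#' Nucleotide diversity per site with its standard deviation
#'
#' pi is the average over all unordered sequence pairs of the per-pair
#' proportion of differing sites (differences divided by the number of sites
#' compared in that pair, under pairwise deletion of N/gap sites). The
#' default standard deviation is the no-recombination total variance
#' (stochastic plus sampling; Nei 1987 eq. 10.7),
#' V(pi) = (n+1)/(3(n-1)) pi/L + 2(n^2+n+3)/(9n(n-1)) pi^2;
#' \code{varMethod = "bootstrap"} instead resamples sequences with
#' replacement for a sampling-only standard deviation.
#'
#' @param aln a \linkS4class{HaploAlignment}, DNAStringSet or character
#'   vector of aligned sequences.
#' @param varMethod "total" (default) or "bootstrap".
#' @param nBoot bootstrap replicates when \code{varMethod = "bootstrap"}.
#' @param seed optional seed for the bootstrap.
#' @return list with elements \code{pi} and \code{sd}.
#' @export
nucleotideDiversity <- function(aln, varMethod = c("total", "bootstrap"),
                                nBoot = 1000, seed = NULL) {
  varMethod <- match.arg(varMethod)
  enc <- if (is(aln, "HaploAlignment")) .encodeSeqs(aln@seqs)
         else .encodeSeqs(aln)
  n <- nrow(enc)
  if (n < 2) stop("insufficient-sample error: need n >= 2")
  pi <- .piFromEnc(enc)
  L <- ncol(enc)
  if (varMethod == "total") {
    v <- (n + 1) / (3 * (n - 1)) * pi / L +
      2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi^2
    sd <- sqrt(v)
  } else {
    sd <- .withSeed(seed, {
      reps <- vapply(seq_len(nBoot), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        .piFromEnc(enc[idx, , drop = FALSE])
      }, numeric(1))
      stats::sd(reps)
    })
  }
  list(pi = pi, sd = sd)
}

.piFromEnc <- function(enc) {
  d <- .pairDiff(enc)
  sh <- attr(d, "shared")
  lt <- lower.tri(d)
  shared <- sh[lt]
  if (any(shared == 0))
    warning("some sequence pairs share no unambiguous sites; pairs dropped")
  ok <- shared > 0
  mean(d[lt][ok] / shared[ok])
}

#' Per-location, per-area and total diversity table
#'
#' One row per location, one pooled row per area (computed on the
#' concatenated samples of its locations, not averaged), and one total row.
#' Columns mirror a standard diversity summary: sample size N, number of
#' haplotypes Nh, number of polymorphic sites Np, haplotype diversity h with
#' S.D., and nucleotide diversity pi with S.D.
#'
#' @param aln a \linkS4class{HaploAlignment}.
#' @param minN groups smaller than this are skipped with a warning.
#' @return data.frame with columns \code{group}, \code{level}, \code{n},
#'   \code{nHap}, \code{nPoly}, \code{h}, \code{hSd}, \code{pi}, \code{piSd}.
#' @export
diversityTable <- function(aln, minN = 2L) {
  stopifnot(is(aln, "HaploAlignment"))
  meta <- as.data.frame(aln@meta)
  groups <- list()
  for (l in unique(meta$location))
    groups[[length(groups) + 1L]] <-
      list(name = l, level = "location", idx = which(meta$location == l))
  areas <- unique(meta$area)
  if (length(areas) > 1L)
    for (a in areas)
      groups[[length(groups) + 1L]] <-
        list(name = a, level = "area", idx = which(meta$area == a))
  groups[[length(groups) + 1L]] <-
    list(name = "TOTAL", level = "total", idx = seq_len(nrow(meta)))
  rows <- lapply(groups, function(g) {
    if (length(g$idx) < minN) {
      warning("group ", g$name, " has fewer than ", minN,
              " sequences; skipped")
      return(NULL)
    }
    sub <- .encodeSeqs(aln@seqs[g$idx])
    sq <- as.character(aln@seqs[g$idx])
    cnt <- as.integer(table(sq))
    hd <- haplotypeDiversity(cnt)
    nd <- nucleotideDiversity(aln@seqs[g$idx])
    data.frame(group = g$name, level = g$level, n = length(g$idx),
               nHap = length(cnt), nPoly = .nPolySites(sub),
               h = hd$h, hSd = hd$sd, pi = nd$pi, piSd = nd$sd,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
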