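# internal helpers shared across modules

.ALPHABET <- c("A", "C", "G", "T", "N", "-")

# encode sequences (DNAStringSet or character) as integer matrix:
# A=1 C=2 G=3 T=4, anything ambiguous (N, -) = 0
.encodeSeqs <- function(seqs) {
  if (is(seqs, "DNAStringSet")) {
    m <- as.matrix(seqs)
  } else {
    nm <- names(seqs)
    seqs <- toupper(as.character(seqs))
    m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
    rownames(m) <- nm
  }
  enc <- matrix(0L, nrow(m), ncol(m), dimnames = list(rownames(m), NULL))
  enc[m == "A"] <- 1L
  enc[m == "C"] <- 2L
  enc[m == "G"] <- 3L
  enc[m == "T"] <- 4L
  enc
}

.decodeSeqs <- function(enc) {
  letters <- c("N", "A", "C", "G", "T")
  m <- matrix(letters[enc + 1L], nrow(enc), ncol(enc))
  out <- apply(m, 1L, paste0, collapse = "")
  names(out) <- rownames(enc)
  out
}

.illegalLetters <- function(seqs) {
  tab <- colSums(Biostrings::alphabetFrequency(seqs))
  used <- names(tab)[tab > 0]
  setdiff(used, .ALPHABET)
}

# log(exp(a) + exp(b)) element-wise, -Inf safe
.logAddExp <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(pmin(a, b) - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

# permutation p-value with the +1 correction
.permP <- function(nExtreme, nPerm) (nExtreme + 1) / (nPerm + 1)

.checkSquare <- function(x, what = "matrix") {
  if (!is.matrix(x) || nrow(x) != ncol(x))
    stop(what, " must be a square matrix")
  if (max(abs(x - t(x))) > 1e-8) stop(what, " must be symmetric")
  if (any(abs(diag(x)) > 1e-8)) stop(what, " must have a zero diagonal")
  if (any(x < 0)) stop(what, " must be non-negative")
  invisible(TRUE)
}

# seed handling: all user-facing stochastic entry points accept seed = NULL
# (use current RNG state) or an integer
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  expr
}

.fmt <- function(x, digits) formatC(x, format = "f", digits = digits)
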