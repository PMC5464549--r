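# fixture builders shared across test files

toyAlignment <- function(seqs, location = "L1", area = "A1") {
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("s%02d", seq_along(seqs))
  names(seqs) <- ids
  HaploAlignment(seqs, data.frame(
    sample_id = ids,
    location = rep_len(location, length(seqs)),
    area = rep_len(area, length(seqs)),
    stringsAsFactors = FALSE))
}

randomAlignment <- function(n, L, letters = c("A", "C", "G", "T"),
                            location = "L1", area = "A1") {
  seqs <- vapply(seq_len(n), function(i)
    paste0(sample(letters, L, replace = TRUE), collapse = ""), "")
  toyAlignment(seqs, location = location, area = area)
}

# a small two-area, four-location alignment with clear structure
structuredToy <- function() {
  base1 <- "AAAAAAAAAA"
  base2 <- "TTTTTAAAAA"
  seqs <- c(
    a1 = base1, a2 = base1, a3 = "AAAAAAAAAT",
    b1 = base1, b2 = "AAAAAAAATT", b3 = base1,
    c1 = base2, c2 = base2, c3 = "TTTTTAAAAT",
    d1 = base2, d2 = "TTTTTAAGAA", d3 = base2)
  HaploAlignment(seqs, data.frame(
    sample_id = names(seqs),
    location = rep(c("L1", "L2", "L3", "L4"), each = 3),
    area = rep(c("North", "South"), each = 6),
    stringsAsFactors = FALSE))
}

# independent brute-force pairwise differences (per-site double loop)
bruteDiff <- function(chars) {
  m <- do.call(rbind, strsplit(chars, ""))
  n <- nrow(m)
  d <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    cnt <- 0L
    for (s in seq_len(ncol(m))) {
      a <- m[i, s]; b <- m[j, s]
      if (a %in% c("A", "C", "G", "T") && b %in% c("A", "C", "G", "T") &&
          a != b) cnt <- cnt + 1L
    }
    d[i, j] <- cnt
  }
  d
}

smallSimConfig <- function(seed = 1L, ...) {
  SimConfig(areas = list(A1 = c(d1 = 10L, d2 = 10L),
                         A2 = c(d3 = 10L, d4 = 10L)),
            theta = 4, migWithin = 5, migBetween = 0,
            expansionTime = 0.5, growthFactor = 50, mergeTime = 3,
            seed = seed, ...)
}
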