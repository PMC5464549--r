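test_that("FASTA + metadata round-trip preserves the alignment", {
  aln <- toyAlignment(c(x1 = "ACGTACGTAA", x2 = "ACGTACGTAT",
                        x3 = "ACGTACGTNN"))
  fa <- tempfile(fileext = ".fasta"); tsv <- tempfile(fileext = ".tsv")
  writeAlignment(aln, fa, tsv)
  back <- readAlignment(fa, tsv)
  expect_s4_class(back, "HaploAlignment")
  expect_equal(length(back), 3L)
  expect_equal(Biostrings::width(sequences(back))[1], 10L)
  expect_identical(as.character(sequences(back)), as.character(sequences(aln)))
  expect_identical(as.data.frame(sampleInfo(back))$location,
                   as.data.frame(sampleInfo(aln))$location)
})

test_that("malformed inputs are rejected with typed errors", {
  expect_error(toyAlignment(c(a = "ACGTACGTAA", b = "ACGTACGTA")),
               "alignment error")
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGRA", ">b", "ACGTA"), fa)
  tsv <- tempfile(fileext = ".tsv")
  utils::write.table(
    data.frame(sample_id = c("a", "b"), location = "L", area = "A"),
    tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readAlignment(fa, tsv), "alphabet error")
  fa2 <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGTA", ">b", "ACGTA", ">c", "ACGTA"), fa2)
  expect_error(readAlignment(fa2, tsv), "metadata error")
})

test_that("a simulated study round-trips through disk with full size", {
  sim <- simulateStudy(defaultSimConfig(seed = 11L))
  fa <- tempfile(fileext = ".fasta"); tsv <- tempfile(fileext = ".tsv")
  writeAlignment(sim$aln, fa, tsv)
  back <- readAlignment(fa, tsv)
  expect_equal(length(back), sim$truth$nSamples)
  expect_equal(length(back), 312L)
  expect_equal(length(unique(as.data.frame(sampleInfo(back))$location)), 13L)
})

test_that("collapseHaplotypes groups exact duplicates and counts singletons", {
  aln <- toyAlignment(c(a = "AAAA", b = "AAAA", c = "AAAA", d = "AAAA",
                        e = "AAAT"))
  ht <- collapseHaplotypes(aln)
  expect_equal(nHaplotypes(ht), 2L)
  expect_equal(sort(rowSums(hapCounts(ht))), c(1, 4),
               ignore_attr = TRUE)
  expect_equal(nSingletons(ht), 1L)

  all5 <- toyAlignment(c(a = "AAAA", b = "AAAT", c = "AATT", d = "ATTT",
                         e = "TTTT"))
  expect_equal(nHaplotypes(collapseHaplotypes(all5)), 5L)
  expect_equal(nSingletons(collapseHaplotypes(all5)), 5L)
})

test_that("zero between-area migration yields no between-area sharing", {
  sim <- simulateStudy(smallSimConfig(seed = 3L))
  ht <- collapseHaplotypes(sim$aln)
  am <- areaMap(ht)
  byArea <- t(rowsum(t(hapCounts(ht)), am[colnames(hapCounts(ht))]))
  expect_true(all(rowSums(byArea > 0) == 1L))
})

test_that("expandFromCounts inverts collapseHaplotypes", {
  ht0 <- collapseHaplotypes(toyAlignment(
    c(a = "GGGG", b = "GGGG", c = "GGGT")))
  aln <- expandFromCounts(ht0)
  expect_equal(length(aln), 3L)
  expect_equal(sort(table(as.character(sequences(aln)))),
               sort(c(GGGG = 2L, GGGT = 1L)), ignore_attr = TRUE)

  # property: round trip over random tables
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(5:40, 1)
    aln0 <- randomAlignment(n, 8, letters = c("A", "T"),
                            location = sample(c("L1", "L2"), n, TRUE))
    ht <- collapseHaplotypes(aln0)
    ht2 <- collapseHaplotypes(expandFromCounts(ht))
    expect_identical(as.character(hapSequences(ht)),
                     as.character(hapSequences(ht2)))
    expect_identical(hapCounts(ht)[, sort(colnames(hapCounts(ht)))],
                     hapCounts(ht2)[, sort(colnames(hapCounts(ht2)))])
  }
})

test_that("haplotype tables with bad counts are rejected", {
  ht <- collapseHaplotypes(toyAlignment(c(a = "AAAA", b = "AAAT")))
  ht@counts[] <- 0L
  expect_error(expandFromCounts(ht), "empty-input")
  ht@counts[1] <- -1L
  expect_error(expandFromCounts(ht), "negative|validation")
})

test_that("a study-shaped count table expands to the full sample size", {
  sizes <- c(24, 24, 24, 25, 18, 24, 24, 24, 24, 24, 29, 24, 24)
  haps <- vapply(seq_len(30), function(i)
    paste0(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = ""), "")
  haps <- unique(haps)
  cm <- matrix(0L, length(haps), 13,
               dimnames = list(sprintf("H%03d", seq_along(haps)),
                               paste0("L", 1:13)))
  set.seed(9)
  for (j in 1:13) {
    left <- sizes[j]
    while (left > 0) {
      i <- sample(length(haps), 1)
      take <- sample(seq_len(left), 1)
      cm[i, j] <- cm[i, j] + take
      left <- left - take
    }
  }
  keep <- rowSums(cm) > 0
  hs <- Biostrings::DNAStringSet(haps[keep])
  names(hs) <- rownames(cm)[keep]
  ht <- new("HaplotypeTable", hapSeqs = hs,
            counts = cm[keep, , drop = FALSE],
            areas = stats::setNames(rep(c("A1", "A2", "A3"), c(4, 7, 2)),
                                    paste0("L", 1:13)))
  aln <- expandFromCounts(ht)
  expect_equal(length(aln), sum(sizes))
  expect_equal(unname(colSums(hapCounts(collapseHaplotypes(aln)))[
    paste0("L", 1:13)]), sizes)
})

test_that("pairwise differences follow the masking rule and match brute force", {
  expect_equal(pairwiseDifferences(c(a = "AAAA", b = "AAAT"))[1, 2], 1L)
  expect_equal(pairwiseDifferences(c(a = "AA-N", b = "AAAT"))[1, 2], 0L)

  set.seed(5)
  chars <- vapply(1:6, function(i)
    paste0(sample(c("A", "C", "G", "T", "N", "-"), 20, TRUE,
                  prob = c(rep(0.22, 4), 0.06, 0.06)), collapse = ""), "")
  d <- pairwiseDifferences(stats::setNames(chars, letters[1:6]))
  expect_equal(unname(unclass(d)), bruteDiff(chars), ignore_attr = TRUE)
  expect_true(isSymmetric(unclass(d)))
  expect_true(all(diag(d) == 0))
  expect_true(all(d <= 20))
})

test_that("pairwise differences agree with an independent distance engine", {
  skip_if_not_installed("ape")
  set.seed(8)
  aln <- randomAlignment(10, 60)
  d <- pairwiseDifferences(aln)
  bin <- ape::as.DNAbin(strsplit(as.character(sequences(aln)), ""))
  dd <- as.matrix(ape::dist.dna(bin, model = "N", pairwise.deletion = TRUE))
  expect_equal(unname(unclass(d)), unname(dd), ignore_attr = TRUE)
})

test_that("polymorphic-site count is invariant under sequence reordering", {
  set.seed(13)
  aln <- randomAlignment(12, 30)
  ht1 <- collapseHaplotypes(aln)
  perm <- sample(length(aln))
  ht2 <- collapseHaplotypes(aln[perm])
  expect_equal(nPolymorphic(ht1), nPolymorphic(ht2))
})
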