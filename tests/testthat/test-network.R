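test_that("two haplotypes one step apart give a single weighted edge", {
  net <- medianJoiningNetwork(collapseHaplotypes(
    toyAlignment(c(a = "AA", b = "AT"))))
  e <- networkEdges(net)
  expect_equal(nrow(e), 1L)
  expect_equal(e$weight, 1L)
  single <- medianJoiningNetwork(collapseHaplotypes(
    toyAlignment(c(a = "ACGT"))))
  expect_equal(nrow(networkEdges(single)), 0L)
  expect_equal(sum(networkNodes(single)$observed), 1L)
})

test_that("the 3-cube toy creates the Steiner median found by exhaustion", {
  # haplotypes 000, 011, 101, 110 coded as A/T strings
  ht <- collapseHaplotypes(toyAlignment(
    c(a = "AAA", b = "ATT", c = "TAT", d = "TTA")))
  net <- medianJoiningNetwork(ht)
  nodes <- networkNodes(net)
  # exhaustive Steiner search over all 2^3 candidates for the triplet
  # {ATT, TAT, TTA}: the cost-3 centre must be TTT
  hapChars <- c("ATT", "TAT", "TTA")
  cands <- apply(expand.grid(rep(list(c("A", "T")), 3)), 1, paste0,
                 collapse = "")
  hd <- function(x, y) sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  costs <- vapply(cands, function(m) sum(vapply(hapChars, hd, 1, x = m)), 1)
  best <- cands[which.min(costs)]
  expect_equal(min(costs), 3)
  expect_equal(best, "TTT")
  expect_true("TTT" %in% nodes$sequence[!nodes$observed])
  # TTT is linked to the three one-step haplotypes
  e <- networkEdges(net)
  ttt <- nodes$id[nodes$sequence == "TTT"]
  touch <- e[e$from == ttt | e$to == ttt, ]
  nb <- setdiff(c(touch$from, touch$to), ttt)
  nbSeq <- nodes$sequence[match(nb, nodes$id)]
  expect_true(all(hapChars %in% nbSeq))
  expect_true(all(touch$weight == 1L))

  # separation {AAA} vs {ATT,TAT,TTA} is 2 (via a median, 1+1)
  part <- stats::setNames(
    ifelse(nodes$sequence[nodes$observed] == "AAA", "g1", "g2"),
    nodes$id[nodes$observed])
  sep <- subnetworkSeparation(net, part)
  expect_equal(sep["g1", "g2"], 2)
})

test_that("separation counts inter-group steps only", {
  net <- medianJoiningNetwork(collapseHaplotypes(
    toyAlignment(c(a = "AAAATTTT", b = "TTTTTTTT"))))
  nodes <- networkNodes(net)
  part <- stats::setNames(c("g1", "g2"), nodes$id)
  expect_equal(subnetworkSeparation(net, part)["g1", "g2"], 4)

  # a haplotype observed in both groups: zero separation
  net2 <- medianJoiningNetwork(collapseHaplotypes(
    toyAlignment(c(a = "AAAA", b = "AATT", c = "TTTT"))))
  ids <- networkNodes(net2)$id[networkNodes(net2)$observed]
  overlap <- list(g1 = ids[1:2], g2 = ids[2:3])
  expect_equal(subnetworkSeparation(net2, overlap)["g1", "g2"], 0)
  expect_error(subnetworkSeparation(net2, list(g1 = "absent", g2 = ids[1])),
               "input error")
})

test_that("isolated simulated areas resolve into matching sub-networks", {
  sim <- simulateStudy(smallSimConfig(seed = 2L))
  ht <- collapseHaplotypes(sim$aln)
  net <- medianJoiningNetwork(ht)
  # area of each observed haplotype from the count matrix (no sharing)
  am <- areaMap(ht)
  byArea <- t(rowsum(t(hapCounts(ht)), am[colnames(hapCounts(ht))]))
  hapArea <- colnames(byArea)[apply(byArea > 0, 1, which)]
  names(hapArea) <- rownames(hapCounts(ht))
  # label every node (medians included) with the area of its nearest
  # observed haplotype, then cut edges joining different areas: the
  # remaining components must separate the areas exactly
  e <- networkEdges(net)
  nodes <- networkNodes(net)
  g <- asIgraph(net)
  dAll <- unclass(pairwiseDifferences(
    stats::setNames(nodes$sequence, nodes$id)))
  obsIds <- names(hapArea)
  nodeArea <- vapply(nodes$id, function(id) {
    hapArea[obsIds[which.min(dAll[id, obsIds])]]
  }, "")
  crossing <- nodeArea[e$from] != nodeArea[e$to]
  g2 <- igraph::delete_edges(g, which(crossing))
  comp <- igraph::components(g2)$membership
  for (a in unique(hapArea)) {
    ids <- obsIds[hapArea == a]
    expect_equal(length(unique(comp[ids])), 1L)
  }
  # no component mixes observed haplotypes from two areas
  expect_true(all(tapply(hapArea, comp[obsIds], function(x)
    length(unique(x))) == 1L))
})

test_that("network is connected and invariant to input order", {
  set.seed(12)
  aln <- randomAlignment(18, 12, letters = c("A", "G", "T"))
  ht <- collapseHaplotypes(aln)
  net <- medianJoiningNetwork(ht)
  g <- asIgraph(net)
  expect_true(igraph::is_connected(g))
  # edge weights bounded below by 1
  expect_true(all(networkEdges(net)$weight >= 1L))
  # shuffled input yields the same edge set up to node relabelling
  perm <- sample(length(aln))
  net2 <- medianJoiningNetwork(collapseHaplotypes(aln[perm]))
  canon <- function(n) {
    nd <- networkNodes(n)
    e <- networkEdges(n)
    a <- nd$sequence[match(e$from, nd$id)]
    b <- nd$sequence[match(e$to, nd$id)]
    sorted <- paste(pmin(a, b), pmax(a, b), e$weight)
    sort(sorted)
  }
  expect_identical(canon(net), canon(net2))
})

test_that("observed haplotypes stay linked within raw-distance bounds", {
  set.seed(33)
  aln <- randomAlignment(12, 10, letters = c("A", "C", "T"))
  ht <- collapseHaplotypes(aln)
  net <- medianJoiningNetwork(ht)
  g <- asIgraph(net)
  d <- unclass(pairwiseDifferences(hapSequences(ht)))
  ids <- names(hapSequences(ht))
  sp <- igraph::distances(g, v = ids, to = ids,
                          weights = networkEdges(net)$weight)
  # every pair is reachable, and path length respects the triangle
  # inequality of the mutational metric (edges are true hamming steps)
  expect_true(all(is.finite(sp)))
  expect_true(all(sp >= d - 1e-9))
})
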