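test_that("Nm follows the haploid island-model identity", {
  expect_equal(round(nmFromFst(0.757), 3), 0.161)
  expect_equal(round(nmFromFst(0.886), 3), 0.064)
  expect_equal(round(nmFromFst(0.596), 3), 0.339)
  expect_equal(nmFromFst(1.0), 0)
  expect_error(nmFromFst(1.2), "domain error")
  expect_warning(nm0 <- nmFromFst(-0.01), "Inf")
  expect_equal(nm0, Inf)
  # strictly decreasing on (0, 1]
  x <- seq(0.01, 1, by = 0.01)
  expect_true(all(diff(nmFromFst(x)) < 0))
})

test_that("fixed differences give FST = 1; panmixia gives FST near 0", {
  aln <- HaploAlignment(
    c(a = "AAAA", b = "AAAA", c = "TTTT", d = "TTTT"),
    data.frame(sample_id = letters[1:4],
               location = rep(c("L1", "L2"), each = 2),
               area = rep(c("X", "Y"), each = 2)))
  pd <- pairwiseFst(aln, level = "area")
  expect_equal(pd@fst["X", "Y"], 1)
  expect_equal(pd@nm["X", "Y"], 0)

  # one panmictic sample split at random into two labels
  set.seed(101)
  fsts <- replicate(60, {
    gen <- HaploGeo:::.coalSingleDeme(40)
    cfg <- SimConfig(areas = list(A = c(d1 = 40L)), theta = 4)
    aln1 <- mutateSequences(gen, cfg, model = "infinite")
    meta <- as.data.frame(sampleInfo(aln1))
    meta$area <- sample(rep(c("X", "Y"), each = 20))
    meta$location <- meta$area
    aln1 <- HaploAlignment(sequences(aln1), meta)
    pairwiseFst(aln1, level = "area")@fst[1, 2]
  })
  expect_lt(abs(mean(fsts)), 0.05)
})

test_that("two-island FST matches the structured-coalescent closed form", {
  # per-lineage emigration rate mig/2 gives FST = 1/(1 + 2 mig) for 2 demes
  set.seed(202)
  mig <- 0.5
  cfg <- SimConfig(areas = list(A = c(d1 = 12L, d2 = 12L)), theta = 3,
                   migWithin = mig, migBetween = 0, expansionTime = 0,
                   growthFactor = 1, mergeTime = Inf)
  hw <- numeric(0); hb <- numeric(0)
  for (r in 1:200) {
    gen <- simulateGenealogy(cfg)
    aln <- mutateSequences(gen, cfg, model = "infinite")
    D <- pairwiseDifferences(aln)
    loc <- as.data.frame(sampleInfo(aln))$location
    i1 <- which(loc == "d1"); i2 <- which(loc == "d2")
    hw <- c(hw, (HaploGeo:::.meanWithin(D, i1) +
                   HaploGeo:::.meanWithin(D, i2)) / 2)
    hb <- c(hb, mean(D[i1, i2]))
  }
  expect_equal(1 - mean(hw) / mean(hb), 1 / (1 + 2 * mig),
               tolerance = 0.15)
})

test_that("AMOVA handles fixed and degenerate toy designs", {
  aln <- HaploAlignment(
    c(a = "AACC", b = "AACC", c = "TTCC", d = "TTCC"),
    data.frame(sample_id = letters[1:4],
               location = rep(c("L1", "L2"), each = 2), area = "X"))
  res <- amova(aln, "two-level", nPerm = 0)
  expect_equal(unname(amovaPhi(res)["phiST"]), 1)
  expect_equal(amovaComponents(res)$pctVariance, c(100, 0),
               tolerance = 1e-9)

  allSame <- toyAlignment(rep("ACGT", 6), location = rep(c("L1", "L2"), 3))
  res0 <- amova(allSame, "two-level", nPerm = 0)
  expect_true(is.na(amovaPhi(res0)["phiST"]))
})

test_that("AMOVA components equal an independent nested-ANOVA oracle", {
  # 2 areas x 2 locations x 3 sequences; oracle computes sums of squares by
  # explicit pair loops and solves the expected-mean-square system directly
  set.seed(31)
  aln <- randomAlignment(12, 15, letters = c("A", "T"))
  meta <- as.data.frame(sampleInfo(aln))
  meta$location <- rep(c("P1", "P2", "P3", "P4"), each = 3)
  meta$area <- rep(c("G1", "G2"), each = 6)
  aln <- HaploAlignment(sequences(aln), meta)
  D <- unclass(pairwiseDifferences(aln))
  attr(D, "shared") <- NULL
  pop <- meta$location; grp <- meta$area
  N <- 12; P <- 4; G <- 2
  pairSum <- function(idx) {
    s <- 0
    for (i in idx) for (j in idx) s <- s + D[i, j]
    s / 2
  }
  ssdT <- pairSum(1:N) / N
  ssdWP <- sum(vapply(unique(pop), function(p)
    pairSum(which(pop == p)) / sum(pop == p), 1))
  ssdWG <- sum(vapply(unique(grp), function(g)
    pairSum(which(grp == g)) / sum(grp == g), 1))
  ssdAG <- ssdT - ssdWG
  ssdAP <- ssdWG - ssdWP
  np <- rep(3, 4); ng <- rep(6, 2)
  A <- sum(tapply(np^2, rep(1:2, each = 2), sum) / ng)
  nP <- (N - A) / (P - G)
  nDp <- (A - sum(np^2) / N) / (G - 1)
  nTp <- (N - sum(ng^2) / N) / (G - 1)
  msWP <- ssdWP / (N - P); msAP <- ssdAP / (P - G); msAG <- ssdAG / (G - 1)
  # solve EMS system: msWP = c; msAP = c + nP b; msAG = c + nDp b + nTp a
  cc <- msWP
  bb <- (msAP - cc) / nP
  aa <- (msAG - cc - nDp * bb) / nTp
  res <- amova(aln, "three-level", nPerm = 0)
  expect_equal(amovaComponents(res)$sigma2, c(aa, bb, cc),
               tolerance = 1e-9)
  expect_equal(sum(amovaComponents(res)$pctVariance), 100, tolerance = 1e-9)
  phi <- amovaPhi(res)
  tot <- aa + bb + cc
  expect_equal(unname(phi["phiCT"]), aa / tot, tolerance = 1e-9)
  expect_equal(unname(phi["phiSC"]), bb / (bb + cc), tolerance = 1e-9)
  expect_equal(unname(phi["phiST"]), (aa + bb) / tot, tolerance = 1e-9)
})

test_that("AMOVA invariants hold on simulated structured data", {
  sim <- simulateStudy(smallSimConfig(seed = 7L))
  res3 <- amova(sim$aln, "three-level", nPerm = 0)
  res2 <- amova(sim$aln, "two-level", nPerm = 0)
  expect_equal(sum(amovaComponents(res3)$pctVariance), 100,
               tolerance = 1e-9)
  expect_equal(sum(amovaComponents(res2)$pctVariance), 100,
               tolerance = 1e-9)
  # the within-location component is design-independent
  expect_equal(amovaComponents(res3)$sigma2[3],
               amovaComponents(res2)$sigma2[2], tolerance = 1e-9)
  # permutation p-values: phiST is significant for this strongly
  # structured set; phiCT permutes whole locations and with only 4
  # locations in 2 areas there are just 3 distinct partitions, so its
  # attainable floor is about 1/3
  resP <- amova(sim$aln, "three-level", nPerm = 99, seed = 1)
  expect_lt(amovaP(resP)["phiST"], 0.05)
  expect_lte(amovaP(resP)["phiCT"], 0.45)
})

test_that("three-level AMOVA warns when areas have no replicate locations", {
  aln <- HaploAlignment(
    c(a = "AAAA", b = "AAAT", c = "TTTT", d = "TTTA"),
    data.frame(sample_id = letters[1:4],
               location = rep(c("L1", "L2"), each = 2),
               area = rep(c("X", "Y"), each = 2)))
  expect_warning(amova(aln, "three-level", nPerm = 0), "degenerate")
})

test_that("Mantel test matches exhaustive enumeration and vegan", {
  x <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  x[lower.tri(x)] <- c(1, 2, 3, 4, 5, 6)
  x <- x + t(x)
  set.seed(4)
  y <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  y[lower.tri(y)] <- sample(1:6)
  y <- y + t(y)

  res <- mantelTest(x, y, exhaustive = TRUE)
  # independent enumeration over all 24 permutations
  lt <- lower.tri(x)
  zobs <- sum(x[lt] * y[lt])
  perms <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
  zs <- apply(perms, 1, function(p) {
    yp <- y[unlist(p), unlist(p)]
    sum(x[lt] * yp[lt])
  })
  expect_equal(res@p, mean(zs >= zobs), tolerance = 1e-12)
  expect_equal(res@z, zobs)

  skip_if_not_installed("vegan")
  set.seed(10)
  n <- 8
  xm <- as.matrix(dist(matrix(rnorm(n * 2), n)))
  ym <- as.matrix(dist(matrix(rnorm(n * 2), n)))
  dimnames(xm) <- dimnames(ym) <- list(paste0("s", 1:n), paste0("s", 1:n))
  ours <- mantelTest(xm, ym, nPerm = 999, seed = 1)
  ref <- vegan::mantel(as.dist(xm), as.dist(ym), permutations = 999)
  expect_equal(ours@r, unname(ref$statistic), tolerance = 1e-9)
  expect_lt(abs(ours@p - ref$signif), 0.12)
})

test_that("identical matrices give r = 1 at the smallest attainable p", {
  x <- matrix(0, 5, 5, dimnames = list(paste0("s", 1:5), paste0("s", 1:5)))
  x[lower.tri(x)] <- 1:10
  x <- x + t(x)
  res <- mantelTest(x, x, exhaustive = TRUE)
  expect_equal(res@r, 1)
  expect_lte(res@p, 2 / factorial(5))  # ties with reflections possible
  y <- x; rownames(y) <- colnames(y) <- paste0("t", 1:5)
  expect_error(mantelTest(x, y), "input error")
})
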