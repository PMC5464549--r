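# Among-sample divergence: pairwise FST/Nm, hierarchical AMOVA, Mantel test

#' Island-model gene flow from FST
#'
#' Effective number of migrants per generation under the haploid
#' (maternally inherited) island model, Nm = (1 - FST) / (2 FST), the
#' inverse of FST = 1 / (1 + 2 Nm).
#'
#' @param fst numeric vector of FST values in (0, 1]. Values <= 0 return
#'   Inf with a warning (no detectable divergence); values > 1 are a
#'   domain error.
#' @return numeric vector of Nm values.
#' @examples
#' nmFromFst(c(0.757, 0.886, 0.596))
#' @export
nmFromFst <- function(fst) {
  if (any(fst > 1, na.rm = TRUE)) stop("domain error: FST > 1")
  out <- ifelse(fst > 0, (1 - fst) / (2 * fst), Inf)
  if (any(fst <= 0, na.rm = TRUE))
    warning("FST <= 0: Nm reported as Inf")
  out
}

#' Pairwise FST and gene flow between groups
#'
#' Default estimator is Hudson/Slatkin's FST = 1 - Hw/Hb, where Hw is the
#' mean within-group pairwise nucleotide difference (averaged over the two
#' groups) and Hb the mean between-group difference. \code{"phi"} instead
#' uses the two-level AMOVA Phi-ST on the group pair (the molecular-variance
#' analogue of Weir and Cockerham's estimator for haplotypic data);
#' \code{"weir"} is accepted as an alias for \code{"phi"}. Negative
#' estimates are reported as computed and clamped only for the Nm
#' conversion. Significance is by permutation of individuals between the two
#' groups.
#'
#' @param aln a \linkS4class{HaploAlignment}.
#' @param level group by "area" or "location".
#' @param estimator "hudson" (default), "phi" or "weir".
#' @param nPerm permutations per pair (0 = no test).
#' @param seed optional integer seed.
#' @return a \linkS4class{PairwiseDivergence}.
#' @export
pairwiseFst <- function(aln, level = c("area", "location"),
                        estimator = c("hudson", "phi", "weir"),
                        nPerm = 0L, seed = NULL) {
  level <- match.arg(level)
  estimator <- match.arg(estimator)
  if (estimator == "weir") estimator <- "phi"
  grp <- as.character(as.data.frame(aln@meta)[[level]])
  labs <- unique(grp)
  if (length(labs) < 2L) stop("need at least 2 groups")
  if (any(table(grp) < 2L))
    stop("insufficient-sample error: every group needs >= 2 sequences")
  D <- pairwiseDifferences(aln)
  k <- length(labs)
  fst <- matrix(0, k, k, dimnames = list(labs, labs))
  p <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
  .withSeed(seed, {
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      ia <- which(grp == labs[a]); ib <- which(grp == labs[b])
      obs <- .fstPair(D, ia, ib, estimator)
      fst[a, b] <- fst[b, a] <- obs
      if (nPerm > 0L) {
        pool <- c(ia, ib); na <- length(ia)
        exceed <- 0L
        for (r in seq_len(nPerm)) {
          prm <- sample(pool)
          f <- .fstPair(D, prm[seq_len(na)], prm[-seq_len(na)], estimator)
          if (!is.na(f) && f >= obs) exceed <- exceed + 1L
        }
        p[a, b] <- p[b, a] <- .permP(exceed, nPerm)
      }
    }
  })
  nm <- matrix(Inf, k, k, dimnames = list(labs, labs))
  pos <- fst > 0
  nm[pos] <- (1 - fst[pos]) / (2 * fst[pos])
  diag(nm) <- 0
  new("PairwiseDivergence", labels = labs, fst = fst, nm = nm, p = p,
      estimator = estimator, nPerm = as.integer(nPerm))
}

.fstPair <- function(D, ia, ib, estimator) {
  if (estimator == "hudson") {
    hw <- (.meanWithin(D, ia) + .meanWithin(D, ib)) / 2
    hb <- mean(D[ia, ib])
    if (hb == 0) return(NA_real_)
    1 - hw / hb
  } else {
    idx <- c(ia, ib)
    pop <- rep(c("a", "b"), c(length(ia), length(ib)))
    comp <- .amovaTwoLevel(D[idx, idx], pop)  # squared distance = raw count
    comp$phi
  }
}

.meanWithin <- function(D, idx) {
  if (length(idx) < 2L) return(NA_real_)
  sub <- D[idx, idx]
  sum(sub) / (length(idx) * (length(idx) - 1))
}

#' @rdname PairwiseDivergence-class
#' @param object a PairwiseDivergence
#' @export
setMethod("show", "PairwiseDivergence", function(object) {
  cat("PairwiseDivergence (", object@estimator, " estimator, ",
      object@nPerm, " permutations)\n", sep = "")
  m <- object@fst
  m[upper.tri(m)] <- object@nm[upper.tri(m)]
  cat("FST below diagonal, Nm above:\n")
  print(round(m, 3))
})

# ---------------------------------------------------------------- AMOVA ----

#' Hierarchical analysis of molecular variance
#'
#' Nested ANOVA on squared molecular distances (Excoffier, Smouse & Quattro
#' 1992), with the pairwise nucleotide-difference count used as the squared
#' Euclidean distance between haplotypes. Sums of squares come from block
#' sums of the distance matrix; variance components are solved from the
#' expected mean squares with unequal-sample-size coefficients. Significance
#' is assessed by permutation: for Phi-ST individuals are permuted among
#' locations over the whole data set, for Phi-SC among locations within
#' their area, and for Phi-CT whole locations are permuted among areas.
#'
#' @param aln a \linkS4class{HaploAlignment}.
#' @param design "two-level" (locations / within locations) or
#'   "three-level" (areas / locations within areas / within locations).
#' @param nPerm number of permutations (default 10000; 0 = no test).
#' @param seed optional integer seed.
#' @return an \linkS4class{AmovaResult}.
#' @export
amova <- function(aln, design = c("two-level", "three-level"),
                  nPerm = 10000L, seed = NULL) {
  design <- match.arg(design)
  meta <- as.data.frame(aln@meta)
  pop <- as.character(meta$location)
  area <- as.character(meta$area)
  D <- pairwiseDifferences(aln)
  storage.mode(D) <- "double"
  if (design == "three-level" && length(unique(area)) < 2L) {
    warning("degenerate design: a single area; falling back to two-level")
    design <- "two-level"
  }
  if (design == "two-level") {
    obs <- .amovaTwoLevel(D, pop)
    comp <- data.frame(
      source = c("Among locations", "Within locations"),
      df = obs$df, sigma2 = obs$sigma2,
      pctVariance = 100 * obs$sigma2 / sum(obs$sigma2))
    phi <- c(phiST = obs$phi)
    p <- c(phiST = NA_real_)
    if (nPerm > 0L && !is.na(obs$phi)) {
      exceed <- 0L
      .withSeed(seed, for (r in seq_len(nPerm)) {
        f <- .amovaTwoLevel(D, sample(pop))$phi
        if (!is.na(f) && f >= obs$phi) exceed <- exceed + 1L
      })
      p["phiST"] <- .permP(exceed, nPerm)
    }
  } else {
    popArea <- tapply(area, pop, function(a) a[1])
    obs <- .amovaThreeLevel(D, pop, popArea)
    comp <- data.frame(
      source = c("Among areas", "Among locations within areas",
                 "Within locations"),
      df = obs$df, sigma2 = obs$sigma2,
      pctVariance = 100 * obs$sigma2 / sum(obs$sigma2))
    phi <- c(phiCT = obs$phiCT, phiSC = obs$phiSC, phiST = obs$phiST)
    p <- c(phiCT = NA_real_, phiSC = NA_real_, phiST = NA_real_)
    if (nPerm > 0L) .withSeed(seed, {
      exCT <- exSC <- exST <- 0L
      areaOfPop <- popArea
      pops <- names(areaOfPop)
      for (r in seq_len(nPerm)) {
        # Phi-CT: permute whole locations among areas
        pa <- areaOfPop; names(pa) <- sample(pops)
        pa <- pa[pops]
        f <- .amovaThreeLevel(D, pop, pa)$phiCT
        if (!is.na(f) && f >= obs$phiCT) exCT <- exCT + 1L
        # Phi-SC: permute individuals among locations within areas
        popSC <- pop
        for (a in unique(area)) {
          i <- which(area == a)
          popSC[i] <- popSC[sample(i)]
        }
        f <- .amovaThreeLevel(D, popSC, areaOfPop)$phiSC
        if (!is.na(f) && f >= obs$phiSC) exSC <- exSC + 1L
        # Phi-ST: permute individuals over the whole data set
        f <- .amovaThreeLevel(D, sample(pop), areaOfPop)$phiST
        if (!is.na(f) && f >= obs$phiST) exST <- exST + 1L
      }
      p["phiCT"] <- .permP(exCT, nPerm)
      p["phiSC"] <- .permP(exSC, nPerm)
      p["phiST"] <- .permP(exST, nPerm)
    })
  }
  new("AmovaResult", design = design, components = comp, phi = phi, p = p,
      nPerm = as.integer(nPerm))
}

# block sums of the squared-distance matrix by population
.blockSums <- function(D, pop) {
  W <- rowsum(D, pop, reorder = TRUE)
  rowsum(t(W), pop, reorder = TRUE)
}

.amovaTwoLevel <- function(D, pop) {
  n <- table(pop)[sort(unique(pop))]
  N <- sum(n); P <- length(n)
  B <- .blockSums(D, pop)
  ssdT <- sum(D) / (2 * N)
  ssdWP <- sum(diag(B) / (2 * as.numeric(n)))
  ssdAP <- ssdT - ssdWP
  dfAP <- P - 1; dfWP <- N - P
  sigC <- ssdWP / dfWP
  nPrime <- (N - sum(n^2) / N) / (P - 1)
  sigA <- (ssdAP / dfAP - sigC) / nPrime
  tot <- sigA + sigC
  phi <- if (abs(tot) < 1e-12) NA_real_ else sigA / tot
  list(sigma2 = c(sigA, sigC), df = c(dfAP, dfWP), phi = phi)
}

.amovaThreeLevel <- function(D, pop, popArea) {
  pops <- sort(unique(pop))
  n <- as.numeric(table(pop)[pops])
  names(n) <- pops
  N <- sum(n); P <- length(n)
  areaOf <- popArea[pops]
  groups <- sort(unique(as.character(areaOf)))
  G <- length(groups)
  B <- .blockSums(D, pop)  # rows/cols in sorted pop order
  ssdT <- sum(D) / (2 * N)
  ssdWP <- sum(diag(B) / (2 * n))
  ng <- tapply(n, areaOf, sum)[groups]
  ssdWG <- sum(vapply(groups, function(g) {
    i <- which(areaOf == g)
    sum(B[i, i]) / (2 * ng[[g]])
  }, numeric(1)))
  ssdAG <- ssdT - ssdWG
  ssdAPWG <- ssdWG - ssdWP
  dfAG <- G - 1; dfAPWG <- P - G; dfWP <- N - P
  sigC <- ssdWP / dfWP
  sumsqg <- tapply(n^2, areaOf, sum)[groups]  # sum of n_p^2 per group
  A <- sum(sumsqg / ng)
  nPrime <- (N - A) / (P - G)
  nDp <- (A - sum(n^2) / N) / (G - 1)
  nTp <- (N - sum(ng^2) / N) / (G - 1)
  sigB <- if (dfAPWG > 0) (ssdAPWG / dfAPWG - sigC) / nPrime else NA_real_
  if (is.na(sigB)) {
    warning("degenerate design: no replicate locations within areas")
    sigB <- 0
  }
  sigA <- (ssdAG / dfAG - sigC - nDp * sigB) / nTp
  tot <- sigA + sigB + sigC
  list(sigma2 = c(sigA, sigB, sigC), df = c(dfAG, dfAPWG, dfWP),
       phiCT = if (abs(tot) < 1e-12) NA_real_ else sigA / tot,
       phiSC = if (abs(sigB + sigC) < 1e-12) NA_real_
               else sigB / (sigB + sigC),
       phiST = if (abs(tot) < 1e-12) NA_real_ else (sigA + sigB) / tot)
}

#' @rdname AmovaResult-class
#' @param object an AmovaResult
#' @export
setMethod("show", "AmovaResult", function(object) {
  cat("AMOVA (", object@design, ", ", object@nPerm,
      " permutations)\n", sep = "")
  df <- object@components
  df$pctVariance <- round(df$pctVariance, 2)
  df$sigma2 <- signif(df$sigma2, 4)
  print(df, row.names = FALSE)
  cat("Phi:", paste(names(object@phi), round(object@phi, 3),
                    sep = " = ", collapse = ", "), "\n")
  if (!all(is.na(object@p)))
    cat("p:  ", paste(names(object@p), signif(object@p, 3),
                      sep = " = ", collapse = ", "), "\n")
})

#' AMOVA accessors
#' @param x an \linkS4class{AmovaResult}
#' @return \code{amovaComponents}: the component table;
#'   \code{amovaPhi}: named Phi-statistics; \code{amovaP}: named p-values.
#' @export
amovaComponents <- function(x) x@components

#' @rdname amovaComponents
#' @export
amovaPhi <- function(x) x@phi

#' @rdname amovaComponents
#' @export
amovaP <- function(x) x@p

# --------------------------------------------------------------- Mantel ----

#' Mantel test of matrix association
#'
#' Z = sum over unordered pairs of X_ij * Y_ij, with the matrix correlation
#' r over the lower triangles. The null distribution is obtained by random
#' simultaneous row/column permutation of one matrix; for n <= 7 all n!
#' permutations can be enumerated exactly.
#'
#' @param x,y symmetric matrices with zero diagonals and identical labels
#'   (dimnames are matched if present).
#' @param nPerm number of random permutations.
#' @param seed optional integer seed.
#' @param exhaustive enumerate all n! permutations (n <= 7 only).
#' @return a \linkS4class{MantelResult}.
#' @export
mantelTest <- function(x, y, nPerm = 10000L, seed = NULL,
                       exhaustive = FALSE) {
  .checkSquare(x, "x"); .checkSquare(y, "y")
  if (nrow(x) != nrow(y)) stop("input error: matrix sizes differ")
  if (!is.null(rownames(x)) && !is.null(rownames(y))) {
    if (!setequal(rownames(x), rownames(y)))
      stop("input error: matrix labels differ")
    y <- y[rownames(x), rownames(x)]
  }
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 labels")
  lt <- lower.tri(x)
  zObs <- sum(x[lt] * y[lt])
  r <- stats::cor(x[lt], y[lt])
  if (exhaustive) {
    if (n > 7L) stop("exhaustive enumeration limited to n <= 7")
    perms <- .allPerms(n)
    zs <- vapply(seq_len(nrow(perms)), function(i) {
      p <- perms[i, ]
      sum(x[lt] * y[p, p][lt])
    }, numeric(1))
    pval <- mean(zs >= zObs)  # includes the identity permutation
    new("MantelResult", z = zObs, r = r, p = pval,
        nPerm = as.integer(nrow(perms)), exhaustive = TRUE)
  } else {
    exceed <- 0L
    .withSeed(seed, for (i in seq_len(nPerm)) {
      p <- sample.int(n)
      if (sum(x[lt] * y[p, p][lt]) >= zObs) exceed <- exceed + 1L
    })
    new("MantelResult", z = zObs, r = r, p = .permP(exceed, nPerm),
        nPerm = as.integer(nPerm), exhaustive = FALSE)
  }
}

.allPerms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .allPerms(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}

#' @rdname MantelResult-class
#' @param object a MantelResult
#' @export
setMethod("show", "MantelResult", function(object) {
  cat("Mantel test: Z =", format(object@z), " r =",
      round(object@r, 4), " P =", signif(object@p, 3),
      if (object@exhaustive) "(exhaustive)" else
        paste0("(", object@nPerm, " permutations)"), "\n")
})
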