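# Structured-coalescent synthetic data generator with HKY+I mutation

#' Construct a simulation scenario
#'
#' @param areas named list; each element a named integer vector of per-deme
#'   sample sizes (element name = area label, vector names = deme labels).
#' @param theta scaled mutation rate per locus (2Nu).
#' @param migWithin,migBetween scaled migration rates on the Nm scale (each
#'   lineage emigrates at rate mig/2 per coalescent time unit; destinations
#'   uniform among the eligible demes).
#' @param expansionTime time (coalescent units) of a sudden expansion;
#'   looking backwards, coalescence is \code{growthFactor} times faster
#'   before it.
#' @param growthFactor expansion magnitude (1 = constant size).
#' @param mergeTime time at which all demes collapse into one ancestral
#'   deme. Must be finite when \code{migBetween = 0} and several areas are
#'   sampled (otherwise the between-area TMRCA is infinite).
#' @param seqLength alignment length (bp).
#' @param baseFreqs HKY stationary base frequencies (A, C, G, T).
#' @param kappa HKY transition/transversion rate ratio.
#' @param pInv proportion of invariant sites.
#' @param seed integer seed (used by \code{\link{simulateStudy}}).
#' @return a \linkS4class{SimConfig}.
#' @export
SimConfig <- function(areas, theta = 6, migWithin = 10, migBetween = 0,
                      expansionTime = 0.6, growthFactor = 150,
                      mergeTime = 4, seqLength = 537L,
                      baseFreqs = c(A = 0.227, C = 0.166,
                                    G = 0.187, T = 0.420),
                      kappa = 5, pInv = 0.7, seed = 1L) {
  areas <- lapply(areas, function(x) {
    y <- as.integer(x); names(y) <- names(x); y
  })
  new("SimConfig", areas = areas, theta = theta, migWithin = migWithin,
      migBetween = migBetween, expansionTime = expansionTime,
      growthFactor = growthFactor, mergeTime = mergeTime,
      seqLength = as.integer(seqLength), baseFreqs = baseFreqs,
      kappa = kappa, pInv = pInv, seed = as.integer(seed))
}

#' Default study-scale scenario
#'
#' Thirteen demes of 18-29 samples grouped in three areas, isolated areas
#' (no between-area migration) that merge into one ancestral deme, and a
#' recent strong expansion, producing star-like within-area genealogies,
#' high haplotype but low nucleotide diversity, no haplotype sharing
#' between areas and strong among-area divergence.
#'
#' @param seed integer seed.
#' @return a \linkS4class{SimConfig}.
#' @export
defaultSimConfig <- function(seed = 1L) {
  SimConfig(
    areas = list(
      NEA = c(SKE = 24L, BIA = 24L, TAN = 24L, AGA = 25L),
      WCM = c(PRT = 18L, BAI = 24L, CSZ = 24L, MLT = 24L,
              GRA = 24L, ZAT = 24L, CAS = 29L),
      ABS = c(VOL = 24L, SOZ = 24L)),
    seed = seed)
}

#' @rdname SimConfig
#' @param object a SimConfig
#' @export
setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", length(unlist(object@areas)), "demes in",
      length(object@areas), "areas,",
      sum(unlist(object@areas)), "samples\n")
  cat("  theta =", object@theta, " migWithin =", object@migWithin,
      " migBetween =", object@migBetween, "\n")
  cat("  expansion t =", object@expansionTime, " x", object@growthFactor,
      "  merge t =", object@mergeTime, "\n")
  cat("  HKY+I: kappa =", object@kappa, " pInv =", object@pInv,
      " L =", object@seqLength, " seed =", object@seed, "\n")
})

#' Simulate a structured-coalescent genealogy
#'
#' Haploid n-island structured coalescent with exponential waiting times.
#' All demes have equal present size (one coalescent unit = N generations);
#' before \code{expansionTime} coalescence is \code{growthFactor} times
#' faster; at \code{mergeTime} all lineages are moved into a single
#' ancestral deme.
#'
#' Uses the current RNG state; seed control belongs to the caller (see
#' \code{\link{simulateStudy}}).
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @return a \linkS4class{Genealogy}.
#' @export
simulateGenealogy <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  demeLabels <- unlist(lapply(cfg@areas, names), use.names = FALSE)
  demeArea <- rep(seq_along(cfg@areas), vapply(cfg@areas, length, 1L))
  sizes <- unlist(cfg@areas, use.names = FALSE)
  nD <- length(demeLabels)
  n <- sum(sizes)
  multiArea <- length(cfg@areas) > 1L
  if (multiArea && cfg@migBetween == 0 && !is.finite(cfg@mergeTime))
    stop("mig_between = 0 with a multi-area sample: between-area TMRCA is ",
         "infinite unless a finite mergeTime is specified")
  if (cfg@migWithin == 0 && any(table(demeArea) > 1L) &&
      cfg@migBetween == 0 && !is.finite(cfg@mergeTime))
    stop("isolated demes require a finite mergeTime")

  nNodes <- 2L * n - 1L
  parent <- integer(nNodes)
  tim <- numeric(nNodes)
  nodeDeme <- integer(nNodes)
  nodeDeme[seq_len(n)] <- rep(seq_len(nD), sizes)
  lin <- seq_len(n)               # active lineage node ids
  linDeme <- nodeDeme[seq_len(n)]
  nxt <- n + 1L
  t <- 0
  bps <- sort(unique(c(
    if (cfg@growthFactor > 1) cfg@expansionTime,
    if (is.finite(cfg@mergeTime)) cfg@mergeTime)))
  merged <- FALSE
  demesInArea <- table(factor(demeArea, levels = seq_along(cfg@areas)))
  while (length(lin) > 1L) {
    factorCoal <- if (cfg@growthFactor > 1 && t >= cfg@expansionTime)
      cfg@growthFactor else 1
    kd <- tabulate(linDeme, nD)
    coalRates <- factorCoal * kd * (kd - 1) / 2
    if (merged) {
      wElig <- logical(length(lin)); bElig <- logical(length(lin))
    } else {
      wElig <- demesInArea[demeArea[linDeme]] > 1L & cfg@migWithin > 0
      bElig <- rep(multiArea && cfg@migBetween > 0, length(lin))
    }
    wTot <- sum(wElig) * cfg@migWithin / 2
    bTot <- sum(bElig) * cfg@migBetween / 2
    R <- sum(coalRates) + wTot + bTot
    if (R <= 0) {
      nb <- bps[bps > t]
      if (!length(nb)) stop("no events possible: infinite TMRCA")
      t <- nb[1L]
      if (is.finite(cfg@mergeTime) && t >= cfg@mergeTime && !merged) {
        merged <- TRUE; linDeme[] <- 1L
      }
      next
    }
    dt <- stats::rexp(1L, R)
    nb <- bps[bps > t]
    if (length(nb) && t + dt > nb[1L]) {
      t <- nb[1L]
      if (is.finite(cfg@mergeTime) && t >= cfg@mergeTime && !merged) {
        merged <- TRUE; linDeme[] <- 1L
      }
      next
    }
    t <- t + dt
    u <- stats::runif(1L, 0, R)
    if (u < sum(coalRates)) {
      d <- sample.int(nD, 1L, prob = coalRates)
      inD <- which(linDeme == d)
      pick <- sample(inD, 2L)
      a <- lin[pick[1L]]; b <- lin[pick[2L]]
      parent[a] <- nxt; parent[b] <- nxt
      tim[nxt] <- t; nodeDeme[nxt] <- d
      lin <- c(lin[-pick], nxt)
      linDeme <- c(linDeme[-pick], d)
      nxt <- nxt + 1L
    } else if (u < sum(coalRates) + wTot) {
      i <- sample(which(wElig), 1L)
      a <- demeArea[linDeme[i]]
      targets <- setdiff(which(demeArea == a), linDeme[i])
      linDeme[i] <- if (length(targets) == 1L) targets
                    else sample(targets, 1L)
    } else {
      i <- sample(which(bElig), 1L)
      a <- demeArea[linDeme[i]]
      targets <- which(demeArea != a)
      linDeme[i] <- if (length(targets) == 1L) targets
                    else sample(targets, 1L)
    }
  }
  new("Genealogy", parent = parent, time = tim, deme = nodeDeme,
      nTips = as.integer(n), demeLabels = demeLabels)
}

# fast single-deme coalescent with an optional sudden expansion
# (rate multiplied by g before time T); returns a Genealogy
.coalSingleDeme <- function(n, expansionTime = Inf, growthFactor = 1) {
  n <- as.integer(n)
  nNodes <- 2L * n - 1L
  parent <- integer(nNodes)
  tim <- numeric(nNodes)
  lin <- seq_len(n)
  t <- 0
  nxt <- n + 1L
  k <- n
  while (k > 1L) {
    past <- is.finite(expansionTime) && t >= expansionTime
    rate <- k * (k - 1) / 2 * (if (past) growthFactor else 1)
    dt <- stats::rexp(1L, rate)
    if (!past && is.finite(expansionTime) && t + dt > expansionTime) {
      t <- expansionTime
      next
    }
    t <- t + dt
    pick <- sample.int(k, 2L)
    parent[lin[pick]] <- nxt
    tim[nxt] <- t
    lin <- c(lin[-pick], nxt)
    k <- k - 1L
    nxt <- nxt + 1L
  }
  new("Genealogy", parent = parent, time = tim,
      deme = rep(1L, nNodes), nTips = as.integer(n), demeLabels = "deme1")
}

#' @rdname Genealogy-class
#' @param object a Genealogy
#' @export
setMethod("show", "Genealogy", function(object) {
  cat("Genealogy:", object@nTips, "tips, TMRCA =",
      signif(max(object@time), 4), "coalescent units\n")
})

# Poisson(theta/2 * branch length) mutation counts per non-root node branch
.branchMutations <- function(gen, theta) {
  nNodes <- length(gen@parent)
  len <- numeric(nNodes)
  nr <- which(gen@parent > 0L)
  len[nr] <- gen@time[gen@parent[nr]] - gen@time[nr]
  m <- integer(nNodes)
  m[nr] <- stats::rpois(length(nr), theta / 2 * len[nr])
  m
}

# children list per node (binary coalescent tree)
.childrenList <- function(gen) {
  nNodes <- length(gen@parent)
  ch <- vector("list", nNodes)
  for (i in which(gen@parent > 0L))
    ch[[gen@parent[i]]] <- c(ch[[gen@parent[i]]], i)
  ch
}

#' Drop mutations on a genealogy and build sequences
#'
#' HKY mode: the root sequence is drawn from the stationary base
#' frequencies, a fixed fraction of sites is flagged invariant, and each
#' branch receives Poisson(theta/2 x length) mutation events scattered
#' uniformly over the variable sites; at each event the new base is drawn
#' with probability proportional to the HKY rates away from the current
#' base (multiple hits allowed). Infinite-sites mode gives every mutation
#' its own site (ancestral state A, derived state T), for analytic checks.
#'
#' Uses the current RNG state (see \code{\link{simulateStudy}} for seeded,
#' reproducible data sets).
#'
#' @param gen a \linkS4class{Genealogy}.
#' @param cfg a \linkS4class{SimConfig}.
#' @param model "hky" (default) or "infinite".
#' @return a \linkS4class{HaploAlignment} (tip order = simulated sample
#'   order; locations = deme labels).
#' @export
mutateSequences <- function(gen, cfg, model = c("hky", "infinite")) {
  model <- match.arg(model)
  n <- gen@nTips
  mut <- .branchMutations(gen, cfg@theta)
  ch <- .childrenList(gen)
  root <- which(gen@parent == 0L)
  if (model == "infinite") {
    S <- sum(mut)
    L <- max(S, 1L)
    seqm <- matrix(1L, n, L)   # all-A ancestral
    if (S > 0L) {
      tips <- .descendantTips(gen, ch)
      col <- 1L
      for (b in which(mut > 0L)) {
        for (r in seq_len(mut[b])) {
          seqm[tips[[b]], col] <- 4L   # derived T
          col <- col + 1L
        }
      }
    }
  } else {
    L <- cfg@seqLength
    variable <- which(stats::runif(L) >= cfg@pInv)
    trans <- c(3L, 4L, 1L, 2L)  # A<->G, C<->T
    targetProb <- matrix(0, 4, 4)
    for (b in 1:4) {
      pr <- cfg@baseFreqs
      pr[trans[b]] <- pr[trans[b]] * cfg@kappa
      pr[b] <- 0
      targetProb[b, ] <- pr / sum(pr)
    }
    seqAll <- matrix(0L, length(gen@parent), L)
    seqAll[root, ] <- sample.int(4L, L, replace = TRUE,
                                 prob = cfg@baseFreqs)
    # top-down traversal
    stack <- root
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (c2 in ch[[v]]) {
        s <- seqAll[v, ]
        if (mut[c2] > 0L && length(variable)) {
          sites <- if (length(variable) == 1L)
            rep(variable, mut[c2])
          else sample(variable, mut[c2], replace = TRUE)
          for (site in sites) {
            b <- s[site]
            s[site] <- sample.int(4L, 1L, prob = targetProb[b, ])
          }
        }
        seqAll[c2, ] <- s
        stack <- c(stack, c2)
      }
    }
    seqm <- seqAll[seq_len(n), , drop = FALSE]
  }
  ids <- sprintf("S%04d", seq_len(n))
  rownames(seqm) <- ids
  strs <- .decodeSeqs(seqm)
  demeIdx <- gen@deme[seq_len(n)]
  areaOfDeme <- rep(names(.areasFromLabels(gen, cfg)),
                    vapply(cfg@areas, length, 1L))
  meta <- data.frame(sample_id = ids,
                     location = gen@demeLabels[demeIdx],
                     area = areaOfDeme[demeIdx],
                     stringsAsFactors = FALSE)
  HaploAlignment(strs, meta)
}

.areasFromLabels <- function(gen, cfg) cfg@areas

# tip index sets below each node
.descendantTips <- function(gen, ch = .childrenList(gen)) {
  nNodes <- length(gen@parent)
  n <- gen@nTips
  tips <- vector("list", nNodes)
  for (i in seq_len(n)) tips[[i]] <- i
  for (v in (n + 1L):nNodes)
    tips[[v]] <- unlist(tips[ch[[v]]], use.names = FALSE)
  tips
}

# histogram (classes 0..max) of pairwise path mutation counts on a
# genealogy, given per-branch mutation counts
.mismatchFromGenealogy <- function(gen, mut) {
  n <- gen@nTips
  ch <- .childrenList(gen)
  nNodes <- length(gen@parent)
  cum <- numeric(nNodes)         # mutations from node up to root
  root <- which(gen@parent == 0L)
  ord <- order(gen@time[(n + 1L):nNodes], decreasing = TRUE) + n
  for (v in c(root, setdiff(ord, root)))
    for (c2 in ch[[v]]) cum[c2] <- cum[v] + mut[c2]
  tips <- .descendantTips(gen, ch)
  diffs <- integer(0)
  maxd <- 0L
  counts <- numeric(1)
  for (v in (n + 1L):nNodes) {
    c12 <- ch[[v]]
    ta <- tips[[c12[1L]]]; tb <- tips[[c12[2L]]]
    dd <- outer(cum[ta], cum[tb], "+") - 2 * cum[v]
    tb2 <- tabulate(as.integer(dd) + 1L)
    if (length(tb2) > length(counts))
      counts <- c(counts, numeric(length(tb2) - length(counts)))
    counts[seq_along(tb2)] <- counts[seq_along(tb2)] + tb2
  }
  counts
}

# mean pairwise differences and number of distinct haplotypes implied by
# per-branch mutation counts (infinite sites)
.summaryFromGenealogy <- function(gen, mut) {
  n <- gen@nTips
  ch <- .childrenList(gen)
  tips <- .descendantTips(gen, ch)
  nNodes <- length(gen@parent)
  nonroot <- which(gen@parent > 0L)
  sz <- vapply(tips, length, 1L)
  pi <- sum(mut[nonroot] * sz[nonroot] * (n - sz[nonroot])) / choose(n, 2)
  # haplotype classes: collapse zero-mutation branches top-down
  cls <- integer(nNodes)
  root <- which(gen@parent == 0L)
  cls[root] <- 1L
  nextCls <- 2L
  ord <- order(gen@time, decreasing = TRUE)
  for (v in ord) {
    if (v == root) next
    if (mut[v] > 0L) { cls[v] <- nextCls; nextCls <- nextCls + 1L }
    else cls[v] <- cls[gen@parent[v]]
  }
  k <- length(unique(cls[seq_len(n)]))
  list(pi = pi, k = k)
}

#' Simulate a full synthetic study
#'
#' Generates a genealogy under the configured structured-coalescent
#' scenario, drops HKY+I mutations, and returns the alignment with sample
#' metadata (locations = demes, areas as configured, synthetic coordinates
#' on a regular grid) plus a truth record of the generating parameters.
#' Fully reproducible: the configured seed drives all randomness, so
#' identical seeds give identical data sets.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @return list with elements \code{aln} (a
#'   \linkS4class{HaploAlignment}), \code{genealogy} and \code{truth}.
#' @export
simulateStudy <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  set.seed(cfg@seed)
  gen <- simulateGenealogy(cfg)
  aln <- mutateSequences(gen, cfg, model = "hky")
  demeLabels <- unlist(lapply(cfg@areas, names), use.names = FALSE)
  meta <- as.data.frame(aln@meta)
  grid <- data.frame(location = demeLabels,
                     lat = 35 + 2 * seq_along(demeLabels),
                     lon = -10 + 3 * seq_along(demeLabels))
  meta$lat <- grid$lat[match(meta$location, grid$location)]
  meta$lon <- grid$lon[match(meta$location, grid$location)]
  aln <- HaploAlignment(sequences(aln), meta)
  truth <- list(
    seed = cfg@seed,
    nSamples = sum(unlist(cfg@areas)),
    demeAreas = rep(names(cfg@areas), vapply(cfg@areas, length, 1L)),
    theta = cfg@theta, migWithin = cfg@migWithin,
    migBetween = cfg@migBetween, expansionTime = cfg@expansionTime,
    growthFactor = cfg@growthFactor, mergeTime = cfg@mergeTime,
    coordinates = "synthetic grid (not real sampling sites)")
  list(aln = aln, genealogy = gen, truth = truth)
}

#' Write/read a simulation scenario as flat key-value text
#'
#' @param cfg a \linkS4class{SimConfig}
#' @param path file path
#' @return \code{writeSimConfig}: the path invisibly;
#'   \code{readSimConfig}: a \linkS4class{SimConfig}.
#' @export
writeSimConfig <- function(cfg, path) {
  lines <- c(
    paste0("areas = ", paste(names(cfg@areas), collapse = ",")),
    unlist(lapply(names(cfg@areas), function(a) c(
      paste0("demes.", a, " = ",
             paste(names(cfg@areas[[a]]), collapse = ",")),
      paste0("sizes.", a, " = ",
             paste(cfg@areas[[a]], collapse = ","))))),
    paste0("theta = ", cfg@theta),
    paste0("mig_within = ", cfg@migWithin),
    paste0("mig_between = ", cfg@migBetween),
    paste0("expansion_time = ", cfg@expansionTime),
    paste0("growth_factor = ", cfg@growthFactor),
    paste0("merge_time = ", cfg@mergeTime),
    paste0("seq_length = ", cfg@seqLength),
    paste0("base_freqs = ", paste(cfg@baseFreqs, collapse = ",")),
    paste0("kappa = ", cfg@kappa),
    paste0("p_inv = ", cfg@pInv),
    paste0("seed = ", cfg@seed))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeSimConfig
#' @export
readSimConfig <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1), 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
  names(vals) <- keys
  areaNames <- strsplit(vals[["areas"]], ",")[[1]]
  areas <- lapply(areaNames, function(a) {
    demes <- strsplit(vals[[paste0("demes.", a)]], ",")[[1]]
    sizes <- as.integer(strsplit(vals[[paste0("sizes.", a)]], ",")[[1]])
    names(sizes) <- demes
    sizes
  })
  names(areas) <- areaNames
  SimConfig(areas,
            theta = as.numeric(vals[["theta"]]),
            migWithin = as.numeric(vals[["mig_within"]]),
            migBetween = as.numeric(vals[["mig_between"]]),
            expansionTime = as.numeric(vals[["expansion_time"]]),
            growthFactor = as.numeric(vals[["growth_factor"]]),
            mergeTime = as.numeric(vals[["merge_time"]]),
            seqLength = as.integer(vals[["seq_length"]]),
            baseFreqs = as.numeric(strsplit(vals[["base_freqs"]],
                                            ",")[[1]]),
            kappa = as.numeric(vals[["kappa"]]),
            pInv = as.numeric(vals[["p_inv"]]),
            seed = as.integer(vals[["seed"]]))
}
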