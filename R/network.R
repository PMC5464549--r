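# Median-joining haplotype network (Bandelt, Forster & Roehl 1999)

#' Median-joining haplotype network
#'
#' Iterates minimum-spanning-network (MSN) construction at tolerance
#' \code{epsilon} with the addition of median (quasi-Steiner) vectors for
#' triplets of mutually linked nodes, until no further median is created;
#' median vectors that end up unused (degree at most 1) are pruned. Median
#' vectors are computed site-wise by majority over the triplet, ties
#' resolved toward the lexicographically first member, so the network is
#' deterministic and invariant to input haplotype order. Edge weights count
#' mutational steps (pairwise differences under the same N/gap masking used
#' throughout the package).
#'
#' @param ht a \linkS4class{HaplotypeTable} (or \linkS4class{HaploAlignment},
#'   collapsed first).
#' @param epsilon connection tolerance (default 0).
#' @param maxIter safety cap on median-joining rounds.
#' @return a \linkS4class{HaploNetwork}.
#' @export
medianJoiningNetwork <- function(ht, epsilon = 0, maxIter = 25L) {
  if (is(ht, "HaploAlignment")) ht <- collapseHaplotypes(ht)
  stopifnot(is(ht, "HaplotypeTable"))
  obsSeqs <- as.character(ht@hapSeqs)
  k0 <- length(obsSeqs)
  if (k0 == 1L) {
    counts <- ht@counts
    return(new("HaploNetwork", nodeSeqs = stats::setNames(obsSeqs,
                                                          names(ht@hapSeqs)),
               observed = TRUE, counts = counts,
               edges = data.frame(from = character(0), to = character(0),
                                  weight = integer(0))))
  }
  seqs <- obsSeqs
  for (iter in seq_len(maxIter)) {
    enc <- .encodeSeqs(stats::setNames(seqs, seq_along(seqs)))
    d <- .pairDiff(enc)
    msn <- .msnEdges(d, seqs, epsilon)
    newMeds <- .medianCandidates(seqs, enc, d, msn, epsilon)
    if (!length(newMeds)) break
    seqs <- c(seqs, newMeds)
  }
  enc <- .encodeSeqs(stats::setNames(seqs, seq_along(seqs)))
  d <- .pairDiff(enc)
  msn <- .msnEdges(d, seqs, epsilon)
  keep <- .pruneMedians(length(seqs), k0, msn)
  seqs <- seqs[keep]
  remap <- match(seq_along(keep), which(keep))
  msn <- msn[keep[msn[, 1L]] & keep[msn[, 2L]], , drop = FALSE]
  msn[, 1L] <- remap[msn[, 1L]]; msn[, 2L] <- remap[msn[, 2L]]
  observed <- seq_along(seqs) <= k0
  medSeqs <- seqs[!observed]
  medIds <- if (length(medSeqs))
    sprintf("MV%02d", rank(medSeqs, ties.method = "first")) else character(0)
  ids <- c(names(ht@hapSeqs), medIds)
  counts <- rbind(ht@counts,
                  matrix(0L, sum(!observed), ncol(ht@counts)))
  rownames(counts) <- ids
  enc <- .encodeSeqs(stats::setNames(seqs, ids))
  dfin <- .pairDiff(enc)
  edges <- data.frame(from = ids[msn[, 1L]], to = ids[msn[, 2L]],
                      weight = pmax(1L, dfin[msn]),
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  new("HaploNetwork", nodeSeqs = stats::setNames(seqs, ids),
      observed = observed, counts = counts, edges = edges)
}

# minimum-spanning network at tolerance epsilon: an edge (u,v) is feasible
# iff d(u,v) <= minimax(u,v) + epsilon, minimax being the largest step on
# the minimax path (computed from a deterministic Kruskal MST with ties
# broken by lexicographic node order)
.msnEdges <- function(d, seqs, epsilon) {
  k <- nrow(d)
  rk <- rank(seqs, ties.method = "first")
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  w <- d[pairs]
  lo <- pmin(rk[pairs[, 1L]], rk[pairs[, 2L]])
  hi <- pmax(rk[pairs[, 1L]], rk[pairs[, 2L]])
  ord <- order(w, lo, hi)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  mstAdj <- vector("list", k)
  for (e in ord) {
    i <- pairs[e, 1L]; j <- pairs[e, 2L]
    ri <- find(i); rj <- find(j)
    if (ri != rj) {
      parent[ri] <- rj
      mstAdj[[i]] <- rbind(mstAdj[[i]], c(j, w[e]))
      mstAdj[[j]] <- rbind(mstAdj[[j]], c(i, w[e]))
    }
  }
  # minimax distances over the MST by DFS from each node
  mm <- matrix(0, k, k)
  for (s in seq_len(k)) {
    visited <- logical(k); visited[s] <- TRUE
    stack <- list(c(s, 0))
    while (length(stack)) {
      top <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      v <- top[1L]; mx <- top[2L]
      nb <- mstAdj[[v]]
      if (!is.null(nb)) for (r in seq_len(nrow(nb))) {
        u <- nb[r, 1L]
        if (!visited[u]) {
          visited[u] <- TRUE
          m2 <- max(mx, nb[r, 2L])
          mm[s, u] <- m2
          stack[[length(stack) + 1L]] <- c(u, m2)
        }
      }
    }
  }
  feas <- which(upper.tri(d) & d <= mm + epsilon, arr.ind = TRUE)
  colnames(feas) <- c("row", "col")
  feas
}

# medians of triplets (u, v, w) where v links both u and w in the MSN
.medianCandidates <- function(seqs, enc, d, msn, epsilon) {
  k <- length(seqs)
  adj <- vector("list", k)
  for (e in seq_len(nrow(msn))) {
    i <- msn[e, 1L]; j <- msn[e, 2L]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  cand <- character(0); cost <- numeric(0)
  existing <- seqs
  for (v in seq_len(k)) {
    nb <- adj[[v]]
    if (length(nb) < 2L) next
    nb <- sort(nb)
    for (a in seq_len(length(nb) - 1L)) for (b in (a + 1L):length(nb)) {
      trip <- c(nb[a], v, nb[b])
      m <- .sitewiseMedian(enc[trip, , drop = FALSE], seqs[trip])
      if (m %in% existing) next
      dm <- .distToAll(m, enc[trip, , drop = FALSE])
      cand <- c(cand, m); cost <- c(cost, sum(dm))
    }
  }
  if (!length(cand)) return(character(0))
  lam <- min(cost)
  unique(cand[cost <= lam + epsilon])
}

.sitewiseMedian <- function(encTrip, seqTrip) {
  ordNames <- order(seqTrip)
  encTrip <- encTrip[ordNames, , drop = FALSE]
  med <- integer(ncol(encTrip))
  for (s in seq_len(ncol(encTrip))) {
    col <- encTrip[, s]
    vals <- col[col > 0L]
    if (!length(vals)) { med[s] <- 0L; next }
    tab <- tabulate(vals, 5L)
    mx <- max(tab)
    winners <- which(tab == mx)
    med[s] <- if (length(winners) == 1L) winners
              else vals[1L]  # tie: lexicographically first member's state
  }
  .decodeSeqs(matrix(med, 1L))[[1L]]
}

.distToAll <- function(seqStr, encOthers) {
  e <- .encodeSeqs(seqStr)
  vapply(seq_len(nrow(encOthers)), function(i) {
    a <- e[1L, ]; b <- encOthers[i, ]
    sum(a > 0L & b > 0L & a != b)
  }, numeric(1))
}

# keep all observed nodes; iteratively drop medians with degree <= 1
.pruneMedians <- function(k, k0, msn) {
  keep <- rep(TRUE, k)
  repeat {
    deg <- integer(k)
    for (e in seq_len(nrow(msn))) {
      i <- msn[e, 1L]; j <- msn[e, 2L]
      if (keep[i] && keep[j]) { deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L }
    }
    drop <- which(keep & seq_len(k) > k0 & deg <= 1L)
    if (!length(drop)) break
    keep[drop] <- FALSE
  }
  keep
}

#' @rdname HaploNetwork-class
#' @export
setMethod("networkEdges", "HaploNetwork", function(x) x@edges)

#' @rdname HaploNetwork-class
#' @export
setMethod("networkNodes", "HaploNetwork", function(x) {
  data.frame(id = names(x@nodeSeqs), sequence = unname(x@nodeSeqs),
             observed = x@observed, count = rowSums(x@counts),
             stringsAsFactors = FALSE)
})

#' @rdname HaploNetwork-class
#' @param object a HaploNetwork
#' @export
setMethod("show", "HaploNetwork", function(object) {
  cat("HaploNetwork:", sum(object@observed), "observed haplotypes,",
      sum(!object@observed), "median vectors,",
      nrow(object@edges), "edges\n")
})

#' Convert a haplotype network to an igraph object
#' @param net a \linkS4class{HaploNetwork}
#' @return an \link[igraph]{igraph} graph with edge attribute weight.
#' @export
asIgraph <- function(net) {
  g <- igraph::graph_from_data_frame(net@edges, directed = FALSE,
    vertices = data.frame(name = names(net@nodeSeqs)))
  g
}

#' Mutational separation between sub-networks
#'
#' For each pair of groups in a partition of the observed haplotypes, the
#' minimum total edge weight over network paths connecting any node of one
#' group to any node of the other, not counting steps internal to either
#' group (edges joining two nodes of the same group cost zero).
#'
#' @param net a \linkS4class{HaploNetwork}.
#' @param partition either a named character vector assigning every
#'   observed node id to a group, or a named list of node-id vectors
#'   (groups may then overlap, e.g. a haplotype sampled in both groups;
#'   overlapping groups are zero steps apart).
#' @return symmetric numeric matrix of separations (mutational steps).
#' @export
subnetworkSeparation <- function(net, partition) {
  obsIds <- names(net@nodeSeqs)[net@observed]
  if (is.list(partition)) {
    members <- lapply(partition, as.character)
  } else {
    if (!all(obsIds %in% names(partition)))
      stop("input error: partition must cover every observed node")
    members <- split(names(partition), as.character(partition))
  }
  if (!all(unlist(members) %in% obsIds))
    stop("input error: group member absent from network")
  groups <- sort(names(members))
  if (length(groups) < 2L) stop("input error: need at least 2 groups")
  ew <- net@edges$weight
  from <- net@edges$from; to <- net@edges$to
  out <- matrix(0, length(groups), length(groups),
                dimnames = list(groups, groups))
  g <- asIgraph(net)
  for (a in seq_len(length(groups) - 1L))
    for (b in (a + 1L):length(groups)) {
      va <- members[[groups[a]]]; vb <- members[[groups[b]]]
      if (length(intersect(va, vb))) next  # shared haplotype: 0 steps
      w <- ew
      internal <- (from %in% va & to %in% va) | (from %in% vb & to %in% vb)
      w[internal] <- 0
      dm <- igraph::distances(g, v = va, to = vb, weights = w)
      out[a, b] <- out[b, a] <- min(dm)
    }
  out
}
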