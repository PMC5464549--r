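# Historical demography: mismatch distributions, sudden-expansion model,
# raggedness, Fu's FS

#' Observed mismatch distribution
#'
#' Histogram over all n(n-1)/2 unordered sequence pairs of the number of
#' pairwise nucleotide differences (pairwise deletion of N/gap sites).
#'
#' @param aln a \linkS4class{HaploAlignment}, DNAStringSet or character
#'   vector of aligned sequences.
#' @return a \linkS4class{MismatchDistribution}.
#' @export
mismatchObserved <- function(aln) {
  enc <- if (is(aln, "HaploAlignment")) .encodeSeqs(aln@seqs)
         else .encodeSeqs(aln)
  n <- nrow(enc)
  if (n < 2) stop("insufficient-sample error: need n >= 2")
  d <- .pairDiff(enc)
  dd <- d[lower.tri(d)]
  counts <- tabulate(dd + 1L, nbins = max(dd) + 1L)
  new("MismatchDistribution", counts = as.numeric(counts),
      freq = counts / sum(counts), n = as.integer(n))
}

.asMismatch <- function(counts) {
  new("MismatchDistribution", counts = as.numeric(counts),
      freq = counts / sum(counts), n = NA_integer_)
}

#' @rdname MismatchDistribution-class
#' @param object a MismatchDistribution
#' @export
setMethod("show", "MismatchDistribution", function(object) {
  cat("MismatchDistribution: classes 0..", length(object@counts) - 1L,
      ", ", sum(object@counts), " pairs\n", sep = "")
})

# equilibrium distribution of pairwise differences,
# F_j(theta) = theta^j / (theta+1)^(j+1)
.equilibriumMismatch <- function(theta, dMax) {
  j <- 0:dMax
  if (theta == 0) return(as.numeric(j == 0))
  exp(j * log(theta) - (j + 1) * log(theta + 1))
}

#' Expected mismatch distribution under the sudden-expansion model
#'
#' Transient distribution of pairwise differences for a population at
#' equilibrium size theta0 that expanded to theta1 at time tau (in
#' mutational units, 2ut) before present:
#' F_j = Fhat_j(theta1) P(j+1, a tau) +
#'       exp(-a tau) sum_k tau^k/k! Fhat_(j-k)(theta0),
#' with a = (theta1+1)/theta1, Fhat the geometric equilibrium distribution
#' and P the regularized lower incomplete gamma function. The vector is
#' truncated at dMax and renormalized; the truncated mass is recorded in
#' the \code{"truncated"} attribute. Limits: tau = 0 recovers the
#' pre-expansion equilibrium Fhat(theta0), and theta0 = theta1 gives the
#' equilibrium Fhat(theta0) for every tau.
#'
#' @param tau expansion time in mutational units (>= 0).
#' @param theta0,theta1 pre- and post-expansion scaled sizes (>= 0).
#' @param dMax largest difference class.
#' @return numeric vector of frequencies over classes 0..dMax.
#' @export
expectedMismatch <- function(tau, theta0, theta1, dMax) {
  if (!all(is.finite(c(tau, theta0, theta1))) ||
      any(c(tau, theta0, theta1) < 0))
    stop("domain error: parameters must be finite and non-negative")
  j <- 0:dMax
  if (theta1 <= 0) {
    # instantaneous coalescence at present: all pairs identical
    f <- as.numeric(j == 0)
    attr(f, "truncated") <- 0
    return(f)
  }
  a <- (theta1 + 1) / theta1
  eq1 <- .equilibriumMismatch(theta1, dMax)
  eq0 <- .equilibriumMismatch(theta0, dMax)
  term1 <- eq1 * stats::pgamma(a * tau, shape = j + 1)
  pois <- stats::dpois(j, tau)           # exp(-tau) tau^k / k!
  conv <- vapply(j, function(jj)
    sum(pois[1:(jj + 1)] * eq0[(jj + 1):1]), numeric(1))
  term2 <- exp(-tau / theta1) * conv     # e^-tau folded into dpois
  f <- term1 + term2
  tot <- sum(f)
  out <- f / tot
  attr(out, "truncated") <- 1 - tot
  out
}

#' Harpending's raggedness index
#'
#' r = sum over i = 1..d+1 of (x_i - x_(i-1))^2 on the relative mismatch
#' frequencies x_0..x_d, with the boundary term x_(d+1) = 0 (d = largest
#' observed difference class).
#'
#' @param obs a \linkS4class{MismatchDistribution} or a numeric vector of
#'   class frequencies (classes 0..d).
#' @return the raggedness index.
#' @export
raggedness <- function(obs) {
  x <- if (is(obs, "MismatchDistribution")) obs@freq else obs / sum(obs)
  x <- c(x, 0)
  sum(diff(x)^2)
}

#' Fit the sudden-expansion model to a mismatch distribution
#'
#' (tau, theta0, theta1) minimize the sum of squared deviations (SSD)
#' between observed and model frequencies (bounded quasi-Newton search with
#' multiple random starts). The SSD significance is a parametric bootstrap:
#' B coalescent samples of size n are simulated under the fitted expansion,
#' each refitted, and p = (#{SSD_sim >= SSD_obs}+1)/(B+1); the raggedness
#' index is tested against the same bootstrap null.
#'
#' @param obs a \linkS4class{MismatchDistribution}.
#' @param n sample size that produced the distribution (defaults to the
#'   recorded one).
#' @param B bootstrap replicates (default 1000; 0 = no test).
#' @param nStarts random optimizer starts (default 20).
#' @param seed optional integer seed.
#' @return an \linkS4class{ExpansionFit}.
#' @export
fitExpansion <- function(obs, n = NULL, B = 1000L, nStarts = 20L,
                         seed = NULL) {
  stopifnot(is(obs, "MismatchDistribution"))
  if (is.null(n)) n <- obs@n
  if (is.na(n)) stop("sample size n is required")
  .withSeed(seed, {
    fit <- .fitSSD(obs@freq, nStarts = nStarts)
    rObs <- raggedness(obs)
    pSsd <- NA_real_; pR <- NA_real_
    tauBoot <- numeric(0)
    if (B > 0L) {
      exS <- 0L; exR <- 0L
      tauBoot <- numeric(B)
      dObs <- length(obs@freq) - 1L
      for (b in seq_len(B)) {
        sim <- .simulateExpansionSample(n, fit$tau, fit$theta0, fit$theta1)
        # compare on the observed class range (pool the upper tail) so the
        # refit cost stays bounded when the fitted theta1 is very large
        if (length(sim) > dObs + 1L) {
          sim <- c(sim[seq_len(dObs)], sum(sim[-seq_len(dObs)]))
        }
        simFreq <- sim / sum(sim)
        refit <- .fitSSD(simFreq, nStarts = max(5L, nStarts %/% 4L),
                         hint = c(fit$tau, fit$theta0, fit$theta1))
        if (refit$ssd >= fit$ssd) exS <- exS + 1L
        if (raggedness(simFreq) >= rObs) exR <- exR + 1L
        tauBoot[b] <- refit$tau
      }
      pSsd <- .permP(exS, B)
      pR <- .permP(exR, B)
    }
    new("ExpansionFit", tau = fit$tau, theta0 = fit$theta0,
        theta1 = fit$theta1, ssd = fit$ssd, pSsd = pSsd,
        raggedness = rObs, pRaggedness = pR,
        expected = fit$expected, observed = obs@freq,
        nBoot = as.integer(B), tauBoot = tauBoot,
        converged = fit$converged)
  })
}

# bounded least-squares fit of (tau, theta0, theta1) to mismatch freqs;
# `hint` adds an extra starting point (e.g. the parent fit in bootstraps)
.fitSSD <- function(freq, nStarts = 20L, hint = NULL) {
  dMax <- length(freq) - 1L
  mbar <- sum((0:dMax) * freq)
  obj <- function(par) {
    f <- expectedMismatch(par[1L], par[2L], par[3L], dMax)
    sum((freq - f)^2)
  }
  lower <- c(0, 0, 0)
  upper <- c(max(4 * mbar, 20), 100, 1e5)
  starts <- list(c(max(mbar, 0.1), max(mbar / 10, 0.01), max(10 * mbar, 5)))
  if (!is.null(hint))
    starts[[2L]] <- pmin(pmax(hint, lower), upper)
  for (s in seq_len(max(nStarts - 1L, 0L)))
    starts[[s + 1L]] <- c(stats::runif(1, 0, max(2 * mbar, 5)),
                          stats::runif(1, 0, max(mbar, 1)),
                          10^stats::runif(1, 0, 4))
  best <- NULL
  for (st in starts) {
    o <- try(stats::optim(st, obj, method = "L-BFGS-B",
                          lower = lower, upper = upper,
                          control = list(maxit = 500)), silent = TRUE)
    if (inherits(o, "try-error")) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best))
    stop("optimizer non-convergence: no start succeeded")
  f <- expectedMismatch(best$par[1L], best$par[2L], best$par[3L], dMax)
  list(tau = best$par[1L], theta0 = best$par[2L], theta1 = best$par[3L],
       ssd = best$value, expected = as.numeric(f),
       converged = best$convergence == 0L)
}

# coalescent sample of size n under the fitted sudden expansion, returning
# the pairwise-difference histogram. Mapping to coalescent units of the
# present size: expansion time t = tau/theta1, growth factor theta1/theta0.
.simulateExpansionSample <- function(n, tau, theta0, theta1) {
  theta1 <- max(theta1, 1e-6)
  g <- if (theta0 <= 1e-9) 1e6 else max(theta1 / theta0, 1)
  tExp <- tau / theta1
  gen <- .coalSingleDeme(n, expansionTime = tExp, growthFactor = g)
  mut <- .branchMutations(gen, theta1)
  .mismatchFromGenealogy(gen, mut)
}

#' @rdname ExpansionFit-class
#' @param object an ExpansionFit
#' @export
setMethod("show", "ExpansionFit", function(object) {
  cat("Sudden-expansion fit: tau =", round(object@tau, 3),
      " theta0 =", signif(object@theta0, 4),
      " theta1 =", signif(object@theta1, 4), "\n")
  cat("  SSD =", signif(object@ssd, 4), " p(SSD) =",
      signif(object@pSsd, 3), "\n")
  cat("  raggedness r =", signif(object@raggedness, 4), " p(r) =",
      signif(object@pRaggedness, 3),
      " (", object@nBoot, "bootstrap replicates )\n")
  if (object@theta0 > object@theta1)
    cat("  note: theta0 > theta1 (contraction-shaped fit)\n")
})

# ------------------------------------------------------------- Fu's FS ----

# log unsigned Stirling numbers of the first kind, row n: |s(n, k)|,
# k = 1..n, computed by the triangular recurrence in log space
.logStirlingRow <- function(n) {
  ls <- 0   # row 1: |s(1,1)| = 1
  if (n == 1L) return(ls)
  for (m in 2:n) {
    prev <- ls
    ls <- numeric(m)
    ls[1L] <- log(m - 1) + prev[1L]
    if (m > 2L)
      ls[2:(m - 1L)] <- .logAddExp(log(m - 1) + prev[2:(m - 1L)],
                                   prev[1:(m - 2L)])
    ls[m] <- prev[m - 1L]
  }
  ls
}

# log Pr(K = k | theta, n) under the Ewens sampling distribution,
# Pr(K=k) = |s(n,k)| theta^k / theta_(n)
.logEwensK <- function(theta, n, lsRow = .logStirlingRow(n)) {
  k <- seq_len(n)
  logRising <- sum(log(theta + 0:(n - 1)))
  lsRow + k * log(theta) - logRising
}

#' Fu's FS neutrality test with coalescent significance
#'
#' theta is estimated by the mean number of pairwise differences; S' is the
#' Ewens-sampling probability of observing at least the observed number of
#' distinct haplotypes, Pr(K >= k | theta, n), computed in log space from
#' unsigned Stirling numbers of the first kind; FS = ln(S'/(1-S')).
#' Significance comes from neutral constant-size coalescent simulations
#' conditioned on theta: p = fraction of simulations with FS at or below
#' the observed value (strongly negative FS indicates expansion).
#'
#' @param aln a \linkS4class{HaploAlignment}, DNAStringSet or character
#'   vector of aligned sequences (n >= 3, polymorphic).
#' @param nSims coalescent replicates (default 1000; 0 = no test).
#' @param seed optional integer seed.
#' @return a \linkS4class{FuFsResult}.
#' @export
fuFs <- function(aln, nSims = 1000L, seed = NULL) {
  enc <- if (is(aln, "HaploAlignment")) .encodeSeqs(aln@seqs)
         else .encodeSeqs(aln)
  n <- nrow(enc)
  if (n < 3) stop("insufficient-sample error: need n >= 3")
  d <- .pairDiff(enc)
  thetaHat <- mean(d[lower.tri(d)])
  strs <- .decodeSeqs(enc)
  k <- length(unique(strs))
  if (thetaHat <= 0 || k <= 1L)
    stop("monomorphic sample: FS undefined")
  lsRow <- .logStirlingRow(n)
  fsObs <- .fsStat(thetaHat, k, n, lsRow)
  p <- NA_real_
  if (nSims > 0L) p <- .withSeed(seed, {
    ex <- 0L
    for (s in seq_len(nSims)) {
      gen <- .coalSingleDeme(n)
      mut <- .branchMutations(gen, thetaHat)
      sm <- .summaryFromGenealogy(gen, mut)
      if (sm$pi <= 0 || sm$k <= 1L) next   # monomorphic: never extreme
      fsSim <- .fsStat(sm$pi, sm$k, n, lsRow)
      if (is.finite(fsSim) && fsSim <= fsObs) ex <- ex + 1L
    }
    .permP(ex, nSims)
  })
  new("FuFsResult", fs = fsObs, p = p, thetaHat = thetaHat,
      k = as.integer(k), n = as.integer(n), nSims = as.integer(nSims))
}

# FS = ln(S'/(1-S')), S' = Pr(K >= k); k = 1 gives S' = 1 and FS = +Inf,
# which callers treat as a flagged boundary
.fsStat <- function(theta, k, n, lsRow = .logStirlingRow(n)) {
  lp <- .logEwensK(theta, n, lsRow)
  mx <- max(lp)
  logTot <- mx + log(sum(exp(lp - mx)))   # ~0, kept for stability
  upper <- lp[k:n]
  mxu <- max(upper)
  logSp <- mxu + log(sum(exp(upper - mxu))) - logTot
  sPrime <- exp(logSp)
  if (sPrime >= 1) return(Inf)
  if (sPrime <= 0) return(-Inf)
  log(sPrime) - log1p(-sPrime)
}

#' @rdname FuFsResult-class
#' @param object a FuFsResult
#' @export
setMethod("show", "FuFsResult", function(object) {
  cat("Fu's FS =", round(object@fs, 3), " p =", signif(object@p, 3),
      " (theta =", round(object@thetaHat, 3), ", k =", object@k,
      ", n =", object@n, ",", object@nSims, "simulations)\n")
})

#' Per-area historical-demography table
#'
#' For sequences pooled by biogeographical area (individual sequences, not
#' haplotypes): sudden-expansion SSD with bootstrap p, raggedness r with
#' bootstrap p, and Fu's FS with its coalescent p.
#'
#' @param aln a \linkS4class{HaploAlignment}.
#' @param B bootstrap replicates for the expansion fit.
#' @param nSims coalescent replicates for FS.
#' @param nStarts optimizer starts for the expansion fit.
#' @param seed optional integer seed.
#' @return data.frame with one row per area: \code{area}, \code{tau},
#'   \code{theta0}, \code{theta1}, \code{ssd}, \code{pSsd}, \code{r},
#'   \code{pR}, \code{fs}, \code{pFs}.
#' @export
demographyTable <- function(aln, B = 1000L, nSims = 1000L, nStarts = 20L,
                            seed = NULL) {
  stopifnot(is(aln, "HaploAlignment"))
  meta <- as.data.frame(aln@meta)
  .withSeed(seed, {
    rows <- lapply(unique(meta$area), function(a) {
      sub <- aln[meta$area == a]
      obs <- mismatchObserved(sub)
      fit <- fitExpansion(obs, n = length(sub), B = B, nStarts = nStarts)
      fs <- fuFs(sub, nSims = nSims)
      data.frame(area = a, tau = fit@tau, theta0 = fit@theta0,
                 theta1 = fit@theta1, ssd = fit@ssd, pSsd = fit@pSsd,
                 r = fit@raggedness, pR = fit@pRaggedness,
                 fs = fs@fs, pFs = fs@p, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
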