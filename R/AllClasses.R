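#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importFrom Biostrings DNAStringSet width
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom S4Vectors DataFrame
#' @importFrom stats setNames
NULL

#' Aligned haploid sequences with per-sample metadata
#'
#' A fixed-length nucleotide alignment (one sequence per sampled individual)
#' together with the sample table that places each individual in a sampling
#' location and a biogeographical area. Alphabet is restricted to
#' A, C, G, T, N and the gap character \code{-}; sites carrying N or a gap are
#' treated as missing in all pairwise comparisons (pairwise deletion).
#'
#' @slot seqs a \link[Biostrings]{DNAStringSet}, all of identical width,
#'   named by sample id.
#' @slot meta a \link[S4Vectors]{DataFrame} with columns \code{sample_id},
#'   \code{location}, \code{area} and optional \code{lat}, \code{lon}
#'   (decimal degrees), one row per sequence, in sequence order.
#' @export
setClass("HaploAlignment",
  representation(seqs = "DNAStringSet", meta = "DataFrame"))

setValidity("HaploAlignment", function(object) {
  msg <- character()
  n <- length(object@seqs)
  if (n == 0L) msg <- c(msg, "alignment contains no sequences")
  w <- unique(Biostrings::width(object@seqs))
  if (length(w) > 1L)
    msg <- c(msg, "all sequences must have identical length")
  ids <- names(object@seqs)
  if (is.null(ids) || anyDuplicated(ids))
    msg <- c(msg, "sequence names must be present and unique")
  bad <- .illegalLetters(object@seqs)
  if (length(bad))
    msg <- c(msg, paste0("illegal characters in sequences: ",
                         paste(bad, collapse = ", ")))
  if (nrow(object@meta) != n)
    msg <- c(msg, "metadata must have one row per sequence")
  need <- c("sample_id", "location", "area")
  if (!all(need %in% colnames(object@meta))) {
    msg <- c(msg, "metadata must contain sample_id, location, area")
  } else {
    if (!identical(as.character(object@meta$sample_id), ids))
      msg <- c(msg, "metadata rows must match sequence names in order")
    la <- unique(data.frame(location = as.character(object@meta$location),
                            area = as.character(object@meta$area)))
    if (anyDuplicated(la$location))
      msg <- c(msg, "each location must map to exactly one area")
  }
  if (length(msg)) msg else TRUE
})

#' Haplotype-by-location count table
#'
#' Distinct sequences (haplotypes) with the number of sampled individuals
#' carrying each haplotype at each location. Column sums are the per-location
#' sample sizes; row sums are haplotype frequencies in the pooled sample.
#'
#' @slot hapSeqs a \link[Biostrings]{DNAStringSet} of pairwise-distinct
#'   haplotype sequences, named by haplotype id.
#' @slot counts integer matrix, haplotypes x locations.
#' @slot areas named character vector mapping each location (column) to its
#'   biogeographical area.
#' @export
setClass("HaplotypeTable",
  representation(hapSeqs = "DNAStringSet", counts = "matrix",
                 areas = "character"))

setValidity("HaplotypeTable", function(object) {
  msg <- character()
  k <- length(object@hapSeqs)
  if (k == 0L) msg <- c(msg, "no haplotypes")
  if (nrow(object@counts) != k)
    msg <- c(msg, "counts must have one row per haplotype")
  if (any(object@counts < 0) || any(object@counts != round(object@counts)))
    msg <- c(msg, "counts must be non-negative integers")
  if (k && any(rowSums(object@counts) < 1))
    msg <- c(msg, "every haplotype must be observed at least once")
  if (anyDuplicated(as.character(object@hapSeqs)))
    msg <- c(msg, "haplotype sequences must be pairwise distinct")
  if (!identical(sort(names(object@areas)), sort(colnames(object@counts))))
    msg <- c(msg, "areas must be named by the count matrix columns")
  if (length(msg)) msg else TRUE
})

#' Median-joining haplotype network
#'
#' Observed haplotypes plus inferred median (intermediate) vectors, linked by
#' edges weighted in mutational steps.
#'
#' @slot nodeSeqs character vector of node sequences (observed haplotypes
#'   first, then median vectors), named by node id.
#' @slot observed logical vector flagging sampled (non-median) nodes.
#' @slot counts matrix of per-location counts for observed nodes (zero rows
#'   for median vectors).
#' @slot edges data.frame with columns \code{from}, \code{to}, \code{weight}
#'   (positive integer mutational steps).
#' @export
setClass("HaploNetwork",
  representation(nodeSeqs = "character", observed = "logical",
                 counts = "matrix", edges = "data.frame"))

setValidity("HaploNetwork", function(object) {
  msg <- character()
  if (length(object@nodeSeqs) != length(object@observed))
    msg <- c(msg, "observed flag must match node count")
  if (nrow(object@counts) != length(object@nodeSeqs))
    msg <- c(msg, "counts must have one row per node")
  if (nrow(object@edges) &&
      (any(object@edges$weight < 1) ||
       any(object@edges$weight != round(object@edges$weight))))
    msg <- c(msg, "edge weights must be positive integers")
  if (length(msg)) msg else TRUE
})

#' Hierarchical AMOVA result
#'
#' Variance components, percentages of total variance, Phi-statistics and
#' permutation p-values for a two-level (locations / within locations) or
#' three-level (areas / locations within areas / within locations) analysis
#' of molecular variance on squared nucleotide-difference distances.
#'
#' @slot design "two-level" or "three-level".
#' @slot components data.frame with columns \code{source}, \code{df},
#'   \code{sigma2}, \code{pctVariance}.
#' @slot phi named numeric vector of Phi-statistics.
#' @slot p named numeric vector of permutation p-values (NA if nPerm = 0).
#' @slot nPerm number of permutations used.
#' @export
setClass("AmovaResult",
  representation(design = "character", components = "data.frame",
                 phi = "numeric", p = "numeric", nPerm = "integer"))

#' Pairwise divergence (FST) and gene flow (Nm) between groups
#'
#' @slot labels group labels.
#' @slot fst symmetric matrix of pairwise FST (zero diagonal; small negative
#'   estimates are reported as computed).
#' @slot nm matrix of island-model effective migrants per generation,
#'   Nm = (1 - FST) / (2 FST); infinite where FST <= 0.
#' @slot p permutation p-values (NA off-diagonal if nPerm = 0).
#' @slot estimator "hudson" or "phi".
#' @slot nPerm number of permutations.
#' @export
setClass("PairwiseDivergence",
  representation(labels = "character", fst = "matrix", nm = "matrix",
                 p = "matrix", estimator = "character", nPerm = "integer"))

#' Mantel test result
#'
#' @slot z Mantel's Z statistic, the sum over unordered pairs of the
#'   products of corresponding entries of the two matrices.
#' @slot r the matrix correlation over the lower triangles.
#' @slot p permutation p-value (upper tail).
#' @slot nPerm number of permutations (n! when exhaustive).
#' @slot exhaustive TRUE if all label permutations were enumerated.
#' @export
setClass("MantelResult",
  representation(z = "numeric", r = "numeric", p = "numeric",
                 nPerm = "integer", exhaustive = "logical"))

#' Mismatch distribution
#'
#' Histogram of pairwise nucleotide differences over all unordered sequence
#' pairs of a sample, in difference classes 0..dMax.
#'
#' @slot counts numeric vector of pair counts, classes 0..dMax.
#' @slot freq relative frequencies (sum to 1).
#' @slot n number of sequences.
#' @export
setClass("MismatchDistribution",
  representation(counts = "numeric", freq = "numeric", n = "integer"))

#' Sudden-expansion model fit to a mismatch distribution
#'
#' Least-squares fit of the sudden-expansion transient mismatch distribution
#' (parameters tau, theta0, theta1) with a parametric-bootstrap test of the
#' sum of squared deviations (SSD) and of the raggedness index.
#'
#' @slot tau expansion time in mutational units (2ut).
#' @slot theta0,theta1 pre- and post-expansion scaled population sizes.
#' @slot ssd observed SSD between observed and fitted mismatch frequencies.
#' @slot pSsd bootstrap p-value of the SSD (NA if B = 0).
#' @slot raggedness observed raggedness index r.
#' @slot pRaggedness bootstrap p-value of r (NA if B = 0).
#' @slot expected fitted model frequencies over classes 0..dMax.
#' @slot observed observed frequencies.
#' @slot nBoot number of bootstrap replicates.
#' @slot tauBoot tau estimates refitted on each bootstrap replicate
#'   (basis for percentile intervals).
#' @slot converged logical optimizer convergence flag.
#' @export
setClass("ExpansionFit",
  representation(tau = "numeric", theta0 = "numeric", theta1 = "numeric",
                 ssd = "numeric", pSsd = "numeric", raggedness = "numeric",
                 pRaggedness = "numeric", expected = "numeric",
                 observed = "numeric", nBoot = "integer",
                 tauBoot = "numeric", converged = "logical"))

#' Fu's FS neutrality test result
#'
#' @slot fs the FS statistic, ln(S'/(1-S')) with S' = Pr(K >= k | theta, n)
#'   under the Ewens sampling distribution.
#' @slot p coalescent p-value, fraction of neutral constant-size simulations
#'   with FS at or below the observed value.
#' @slot thetaHat mean number of pairwise differences used as theta.
#' @slot k observed number of distinct haplotypes.
#' @slot n sample size.
#' @slot nSims number of coalescent simulations.
#' @export
setClass("FuFsResult",
  representation(fs = "numeric", p = "numeric", thetaHat = "numeric",
                 k = "integer", n = "integer", nSims = "integer"))

#' Structured-coalescent simulation scenario
#'
#' A haploid island-model scenario with demes (sampling locations) nested in
#' areas, optional sudden expansion, and an HKY+I mutation model.
#' Migration rates are on the Nm scale (effective migrants per generation):
#' each lineage emigrates at rate mig/2 per coalescent time unit (N
#' generations), so for two demes Hudson's FST equals 1/(1 + 2 Nm).
#'
#' @slot areas named list; each element is a named integer vector of
#'   per-deme sample sizes, the element name being the area label.
#' @slot theta scaled mutation rate per locus (2Nu).
#' @slot migWithin scaled migration rate (Nm) among demes within an area.
#' @slot migBetween scaled migration rate (Nm) among areas.
#' @slot expansionTime time of the sudden expansion, coalescent units
#'   (0 = none when growthFactor is 1).
#' @slot growthFactor factor by which population size grew at the expansion
#'   (backwards in time, coalescence is growthFactor times faster earlier).
#' @slot mergeTime time at which all demes collapse into a single ancestral
#'   deme; required finite when migBetween is 0 and several areas are
#'   sampled, otherwise the between-area TMRCA would be infinite.
#' @slot seqLength alignment length in bp.
#' @slot baseFreqs HKY equilibrium base frequencies (A, C, G, T).
#' @slot kappa HKY transition/transversion rate ratio.
#' @slot pInv proportion of invariant sites.
#' @slot seed integer random seed.
#' @export
setClass("SimConfig",
  representation(areas = "list", theta = "numeric", migWithin = "numeric",
                 migBetween = "numeric", expansionTime = "numeric",
                 growthFactor = "numeric", mergeTime = "numeric",
                 seqLength = "integer", baseFreqs = "numeric",
                 kappa = "numeric", pInv = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (!length(object@areas) || is.null(names(object@areas)))
    msg <- c(msg, "areas must be a named list")
  sizes <- unlist(object@areas, use.names = FALSE)
  if (any(sizes < 1)) msg <- c(msg, "per-deme sample sizes must be >= 1")
  demes <- unlist(lapply(object@areas, names), use.names = FALSE)
  if (is.null(demes) || anyDuplicated(demes))
    msg <- c(msg, "deme labels must be present and unique across areas")
  if (object@theta < 0 || object@migWithin < 0 || object@migBetween < 0)
    msg <- c(msg, "rates must be non-negative")
  if (abs(sum(object@baseFreqs) - 1) > 1e-8 || length(object@baseFreqs) != 4L)
    msg <- c(msg, "baseFreqs must be 4 frequencies summing to 1")
  if (object@pInv < 0 || object@pInv >= 1)
    msg <- c(msg, "pInv must be in [0, 1)")
  if (object@growthFactor < 1)
    msg <- c(msg, "growthFactor must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Simulated genealogy
#'
#' A coalescent tree for n sampled lineages: tips are nodes 1..n, internal
#' nodes n+1..2n-1 in coalescence order, the last node being the root.
#'
#' @slot parent integer parent index per node (0 for the root).
#' @slot time node time in coalescent units (0 for tips).
#' @slot deme deme index of each node at its creation.
#' @slot nTips number of sampled lineages.
#' @slot demeLabels deme labels in index order.
#' @export
setClass("Genealogy",
  representation(parent = "integer", time = "numeric", deme = "integer",
                 nTips = "integer", demeLabels = "character"))
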