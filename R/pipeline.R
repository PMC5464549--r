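# Orchestration: full analysis from one configuration, with provenance

#' Run the full phylogeographic analysis pipeline
#'
#' From an alignment + metadata (or a simulation scenario), computes and
#' writes: the per-location/area diversity table, two- and three-level
#' AMOVA tables, the pairwise FST/Nm matrix between areas, the Mantel test
#' of isolation by distance between locations, the median-joining network
#' (edge list + node table), per-area mismatch curves (observed and fitted
#' expansion model), the per-area demography table, and a provenance log.
#' Numeric cells follow the usual reporting precision (h to 3 d.p., pi to
#' 4 d.p., percentages to 2 d.p., Phi to 3 d.p.); full precision is kept in
#' the returned objects.
#'
#' @param fasta,metadata input paths (alternative to \code{simConfig}).
#' @param simConfig a \linkS4class{SimConfig} or path to a scenario file;
#'   when given, data are simulated instead of read.
#' @param outDir output directory (created if needed).
#' @param geoDist optional path to a TSV matrix of between-location
#'   distances (km); when absent, great-circle distances are derived from
#'   the metadata coordinates and labelled as such.
#' @param fstEstimator "hudson" (default), "phi" or "weir".
#' @param nPerm permutations for AMOVA / FST / Mantel.
#' @param bootstrapB bootstrap replicates for the expansion fit.
#' @param nSims coalescent replicates for Fu's FS.
#' @param seed integer seed controlling all randomness of the run.
#' @return invisibly, a list with every result object and the paths
#'   written.
#' @export
runPipeline <- function(fasta = NULL, metadata = NULL, simConfig = NULL,
                        outDir = "haplogeo-out", geoDist = NULL,
                        fstEstimator = "hudson", nPerm = 1000L,
                        bootstrapB = 1000L, nSims = 1000L, seed = 1L) {
  stage <- "input"
  result <- list()
  paths <- character(0)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(outDir, name)
  emit <- function(df, name, digits = NULL) {
    if (!is.null(digits))
      for (col in names(digits))
        if (col %in% colnames(df))
          df[[col]] <- .fmt(df[[col]], digits[[col]])
    utils::write.table(df, out(name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <<- c(paths, out(name))
  }
  tryCatch({
    if (!is.null(simConfig)) {
      cfg <- if (is(simConfig, "SimConfig")) simConfig
             else readSimConfig(simConfig)
      cfg@seed <- as.integer(seed)
      sim <- simulateStudy(cfg)
      aln <- sim$aln
      writeAlignment(aln, out("simulated.fasta"), out("simulated_meta.tsv"))
      jsonlite::write_json(sim$truth, out("truth.json"), auto_unbox = TRUE,
                           digits = NA)
      paths <- c(paths, out("simulated.fasta"), out("simulated_meta.tsv"),
                 out("truth.json"))
    } else {
      if (is.null(fasta) || is.null(metadata))
        stop("need either fasta+metadata or simConfig")
      aln <- readAlignment(fasta, metadata)
    }
    result$aln <- aln
    meta <- as.data.frame(sampleInfo(aln))
    set.seed(as.integer(seed))

    stage <- "diversity"
    divT <- diversityTable(aln)
    result$diversity <- divT
    emit(divT, "diversity.tsv",
         digits = list(h = 3, hSd = 3, pi = 4, piSd = 4))

    stage <- "amova"
    multiArea <- length(unique(meta$area)) > 1L
    am2 <- amova(aln, "two-level", nPerm = nPerm)
    result$amovaTwoLevel <- am2
    emit(.amovaAsTable(am2), "amova_two_level.tsv")
    if (multiArea) {
      am3 <- amova(aln, "three-level", nPerm = nPerm)
      result$amovaThreeLevel <- am3
      emit(.amovaAsTable(am3), "amova_three_level.tsv")
    } else {
      warning("single area: three-level AMOVA skipped")
    }

    stage <- "fst"
    level <- if (multiArea) "area" else "location"
    pd <- pairwiseFst(aln, level = level, estimator = fstEstimator,
                      nPerm = nPerm)
    result$pairwiseDivergence <- pd
    m <- pd@fst
    m[upper.tri(m)] <- pd@nm[upper.tri(m)]
    emit(data.frame(group = rownames(m), round(m, 3),
                    check.names = FALSE), "fst_nm.tsv")

    stage <- "mantel"
    if (length(unique(meta$location)) >= 3L) {
      fstLoc <- pairwiseFst(aln, level = "location", nPerm = 0L)
      fm <- fstLoc@fst
      fm[fm < 0] <- 0
      gd <- if (!is.null(geoDist)) {
        gm <- as.matrix(utils::read.delim(geoDist, row.names = 1L,
                                          check.names = FALSE))
        gm[rownames(fm), rownames(fm)]
      } else if (all(c("lat", "lon") %in% colnames(meta)) &&
                 !anyNA(meta$lat)) {
        greatCircleDistances(meta)[rownames(fm), rownames(fm)]
      } else NULL
      if (!is.null(gd)) {
        mt <- mantelTest(fm, gd, nPerm = nPerm)
        result$mantel <- mt
        emit(data.frame(z = mt@z, r = mt@r, p = mt@p, nPerm = mt@nPerm),
             "mantel.tsv")
      }
    }

    stage <- "network"
    ht <- collapseHaplotypes(aln)
    result$haplotypeTable <- ht
    net <- medianJoiningNetwork(ht)
    result$network <- net
    emit(networkEdges(net), "network_edges.tsv")
    emit(networkNodes(net), "network_nodes.tsv")

    stage <- "demography"
    dem <- demographyTable(aln, B = bootstrapB, nSims = nSims)
    result$demography <- dem
    emit(dem, "demography.tsv",
         digits = list(ssd = 4, pSsd = 4, r = 4, pR = 4, fs = 3, pFs = 4))
    curves <- do.call(rbind, lapply(unique(meta$area), function(a) {
      sub <- aln[meta$area == a]
      obs <- mismatchObserved(sub)
      row <- dem[dem$area == a, ]
      exp <- expectedMismatch(row$tau, row$theta0, row$theta1,
                              length(obs@freq) - 1L)
      data.frame(area = a, class = seq_along(obs@freq) - 1L,
                 observed = obs@freq, expected = as.numeric(exp))
    }))
    emit(curves, "mismatch_curves.tsv")

    stage <- "provenance"
    prov <- list(
      package = "HaploGeo",
      version = as.character(utils::packageVersion("HaploGeo")),
      rVersion = R.version.string,
      seed = seed, nPerm = nPerm, bootstrapB = bootstrapB, nSims = nSims,
      fstEstimator = fstEstimator,
      distanceHandling = "pairwise deletion of N/gap sites",
      fstDefinition = "Hudson 1-Hw/Hb; Nm=(1-FST)/(2FST) haploid island",
      geoDistances = if (!is.null(geoDist)) "user-supplied"
                     else "great-circle fallback (Haversine, km)",
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    jsonlite::write_json(prov, out("provenance.json"), auto_unbox = TRUE)
    paths <- c(paths, out("provenance.json"))
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  result$paths <- paths
  invisible(result)
}

.amovaAsTable <- function(am) {
  df <- am@components
  df$pctVariance <- .fmt(df$pctVariance, 2)
  df$sigma2 <- signif(df$sigma2, 5)
  phiRows <- data.frame(
    source = paste0("Phi_", sub("phi", "", names(am@phi))),
    df = NA, sigma2 = round(am@phi, 3), pctVariance = signif(am@p, 4))
  colnames(phiRows) <- colnames(df)
  rbind(df, phiRows)
}
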