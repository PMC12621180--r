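#' Analysis run configuration
#'
#' Central container for the pipeline's tunable parameters. Defaults are
#' the standard analysis constants: 5-SD detection threshold, 10-s
#' baseline window, 21-point/3rd-order smoothing, top-20% responder
#' fraction, 100 permutations, and a neighbour-influence / lag window of
#' 3x the median event FDHM.
#'
#' @param frameRate sampling rate (Hz).
#' @param stimulusOnset stimulus onset (s) or NA.
#' @param thresholdMultiple detection threshold in baseline SDs.
#' @param baselineSpan baseline window length (s).
#' @param smoothWindow,smoothOrder Savitzky-Golay parameters.
#' @param responderFraction top fraction of cells kept as responders.
#' @param nPerm number of permutations for every null model.
#' @param windowMultiple FDHM multiple for the influence / lag window.
#' @param mergeGap sub-threshold merge gap (s) in event detection.
#' @param alpha concave-hull concavity parameter (px); NULL = automatic.
#' @param encodingFactor fold difference required to call an encoding.
#' @param rngSeed master seed; each randomized stage consumes a seed
#'   derived from it.
#' @return list of class \code{runConfig}.
#' @export
runConfig <- function(frameRate = 10, stimulusOnset = 20,
                      thresholdMultiple = 5, baselineSpan = 10,
                      smoothWindow = 21, smoothOrder = 3,
                      responderFraction = 0.2, nPerm = 100,
                      windowMultiple = 3, mergeGap = 0.5, alpha = NULL,
                      encodingFactor = 2, rngSeed = 1L) {
  cfg <- list(frameRate = frameRate, stimulusOnset = stimulusOnset,
              thresholdMultiple = thresholdMultiple,
              baselineSpan = baselineSpan, smoothWindow = smoothWindow,
              smoothOrder = smoothOrder,
              responderFraction = responderFraction, nPerm = nPerm,
              windowMultiple = windowMultiple, mergeGap = mergeGap,
              alpha = alpha, encodingFactor = encodingFactor,
              rngSeed = rngSeed)
  stopifnot(frameRate > 0, thresholdMultiple > 0, baselineSpan > 0,
            responderFraction > 0, responderFraction <= 1, nPerm >= 1)
  class(cfg) <- "runConfig"
  cfg
}

#' Read a label mask from TIFF, PNG or delimited text
#'
#' @param path file path (.tif/.tiff, .png, or text matrix).
#' @return integer label matrix.
#' @export
readLabelMask <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    m <- tiff::readTIFF(path, as.is = TRUE)
  } else if (ext == "png") {
    m <- round(png::readPNG(path) * 65535)
  } else {
    m <- as.matrix(utils::read.table(path))
    dimnames(m) <- NULL
  }
  storage.mode(m) <- "integer"
  m
}

#' Write a label mask
#'
#' 16-bit TIFF or PNG for image extensions, otherwise a plain text matrix.
#'
#' @param mask integer label matrix.
#' @param path output path.
#' @export
writeLabelMask <- function(mask, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16)
  } else if (ext == "png") {
    png::writePNG(mask / 65535, path)
  } else {
    utils::write.table(mask, path, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a trace table (time column + one column per cell)
#'
#' @param path delimited text file; first column is time in seconds,
#'   remaining column names are cell ids.
#' @param stimulusOnset stimulus onset (s) carried into the TraceSet.
#' @return a \linkS4class{TraceSet}.
#' @export
readTraces <- function(path, stimulusOnset = NA) {
  df <- utils::read.csv(path, check.names = FALSE)
  tm <- df[[1]]
  if (any(diff(tm) <= 0)) stop("time column is not strictly increasing")
  dts <- diff(tm)
  if (max(dts) - min(dts) > 1e-6 * stats::median(dts))
    stop("time grid is not uniform")
  fr <- 1 / stats::median(dts)
  vals <- as.matrix(df[, -1, drop = FALSE])
  TraceSet(vals, fr, stimulusOnset)
}

#' Write a trace table
#'
#' @param traces a \linkS4class{TraceSet}.
#' @param path output csv path.
#' @export
writeTraces <- function(traces, path) {
  df <- data.frame(time = timePoints(traces), check.names = FALSE)
  vals <- traceMatrix(traces)
  for (id in colnames(vals)) df[[id]] <- vals[, id]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write simulation ground truth as JSON
#'
#' @param sensitivity per-cell sensitivity factor.
#' @param events ground-truth event table.
#' @param path output json path.
#' @export
writeGroundTruth <- function(sensitivity, events, path) {
  obj <- list(
    sensitivity = as.list(stats::setNames(as.character(sensitivity),
                                          names(sensitivity))),
    events = events
  )
  jsonlite::write_json(obj, path, dataframe = "columns", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write / read a run configuration as YAML
#'
#' Round-trippable key/value text representation.
#'
#' @param config a \code{runConfig} or \linkS4class{SimulationConfig}.
#' @param path file path.
#' @export
writeConfig <- function(config, path) {
  if (methods::is(config, "SimulationConfig")) {
    sl <- methods::slotNames(config)
    obj <- stats::setNames(lapply(sl, function(s)
      methods::slot(config, s)), sl)
    obj$.class <- "SimulationConfig"
  } else {
    obj <- unclass(config)
    obj$.class <- "runConfig"
  }
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname writeConfig
#' @export
readConfig <- function(path) {
  obj <- yaml::read_yaml(path)
  cls <- obj$.class
  obj$.class <- NULL
  if (identical(cls, "SimulationConfig")) {
    do.call(simulationConfig, obj)
  } else {
    obj$alpha <- obj$alpha %||% NULL
    do.call(runConfig, obj)
  }
}

#' Read and validate pipeline inputs
#'
#' Loads the label mask and trace table and checks that every trace
#' column matches a mask label (offenders are named in the error).
#'
#' @param maskPath label mask file.
#' @param tracePath trace csv file.
#' @param config a \code{runConfig}.
#' @return list with \code{mask} and \code{traces}.
#' @export
readInputs <- function(maskPath, tracePath, config = runConfig()) {
  mask <- readLabelMask(maskPath)
  traces <- readTraces(tracePath, config$stimulusOnset)
  labs <- as.character(sort(unique(as.vector(mask))))
  labs <- labs[labs != "0"]
  missing <- setdiff(cellIds(traces), labs)
  if (length(missing))
    stop("trace columns with no mask label: ",
         paste(missing, collapse = ", "))
  list(mask = mask, traces = traces)
}

#' Run the full analysis pipeline on one or two agonist datasets
#'
#' Executes, per dataset: event detection, cell summaries, responder
#' selection, community partition with clustering permutation null,
#' centrality table; then (with two datasets) group centrality with its
#' null, responder overlap, neighbour influence with the temporal
#' permutation null, and within/between cross-correlation summaries.
#' Every randomized stage consumes a seed derived from
#' \code{config$rngSeed}, so identical inputs give identical outputs.
#'
#' @param mask integer label mask.
#' @param tracesByAgonist named list of \linkS4class{TraceSet} objects
#'   (one per agonist dataset; 1 or 2 entries).
#' @param config a \code{runConfig}.
#' @param stages character vector of stages to run (subset of
#'   "detect", "communities", "centrality", "influence", "xcorr");
#'   "all" runs everything. The graph is always built.
#' @param outDir optional directory; when given, every stage's tables are
#'   written as delimited text / JSON together with the config snapshot.
#' @return nested result list.
#' @export
runPipeline <- function(mask, tracesByAgonist, config = runConfig(),
                        stages = "all", outDir = NULL) {
  if (identical(stages, "all"))
    stages <- c("detect", "communities", "centrality", "influence",
                "xcorr")
  agonists <- names(tracesByAgonist)
  graph <- buildTissueGraph(mask, alpha = config$alpha)
  interior <- interiorCells(graph)
  res <- list(graph = graph, config = config,
              graphStats = graphStats(graph), perAgonist = list())
  need <- function(s) s %in% stages
  if (any(c("detect", "communities", "centrality", "influence",
            "xcorr") %in% stages)) {
    for (ag in agonists) {
      ts <- tracesByAgonist[[ag]]
      ev <- detectEvents(ts, threshold = config$thresholdMultiple,
                         span = config$baselineSpan,
                         window = config$smoothWindow,
                         order = config$smoothOrder,
                         mergeGap = config$mergeGap)
      exposure <- c(if (is.na(stimulusOnset(ts))) 0
                    else stimulusOnset(ts),
                    nrow(traceMatrix(ts)) / frameRate(ts))
      summ <- summarizeCells(ev, interior, exposure)
      resAg <- list(events = ev, summaries = summ)
      if (need("communities") || need("influence") || need("xcorr")) {
        responders <- selectTopResponders(summ, config$responderFraction)
        partition <- findCommunities(graph, responders)
        resAg$responders <- responders
        resAg$partition <- partition
        resAg$metrics <- communityMetrics(graph, partition)
        if (need("communities"))
          resAg$clusteringNull <- clusteringPermutationNull(
            graph, responders, nPerm = config$nPerm,
            seed = deriveSeed(config$rngSeed, 41 + match(ag, agonists)))
      }
      res$perAgonist[[ag]] <- resAg
    }
  }
  if (need("centrality")) {
    res$centrality <- centralityTable(graph)
    if (length(agonists) == 2) {
      ra <- res$perAgonist[[1]]$responders
      rb <- res$perAgonist[[2]]$responders
      res$groupCentrality <- groupCentrality(res$centrality, ra, rb,
                                             labels = paste0(agonists,
                                                             "-only"))
      groups <- list(setdiff(ra, rb), setdiff(rb, ra), intersect(ra, rb))
      names(groups) <- c(paste0(agonists, "-only"), "multisensitive")
      res$centralityNull <- centralityPermutationNull(
        graph, groups[lengths(groups) > 0], nPerm = config$nPerm,
        seed = deriveSeed(config$rngSeed, 51), table = res$centrality)
      res$overlap <- overlapAnalysis(ra, rb, length(interior),
                                     labels = agonists)
    }
  }
  if (need("influence")) {
    for (ag in agonists) {
      ev <- res$perAgonist[[ag]]$events
      if (sum(ev$fit_ok) == 0) next
      tw <- influenceWindow(ev, config$windowMultiple)
      cases <- buildCases(ev, graph, tw, res$perAgonist[[ag]]$partition)
      res$perAgonist[[ag]]$influence <- list(
        tw = tw, cases = cases,
        curve = probabilityByK(cases),
        characteristics = characteristicsByK(cases),
        null = temporalPermutationNull(
          ev, graph, tw, nPerm = config$nPerm,
          seed = deriveSeed(config$rngSeed, 61 + match(ag, agonists)),
          partition = res$perAgonist[[ag]]$partition))
    }
  }
  if (need("xcorr") && length(agonists) == 2) {
    evAll <- do.call(rbind, lapply(res$perAgonist, `[[`, "events"))
    if (sum(evAll$fit_ok) > 0) {
      maxLag <- influenceWindow(evAll, config$windowMultiple)
      segs <- alignAndWindow(tracesByAgonist,
                             baselineSpan = config$baselineSpan)
      ra <- res$perAgonist[[1]]$responders
      rb <- res$perAgonist[[2]]$responders
      within <- xcorrMatrix(segs[[1]], ra, maxLag)
      between <- xcorrBetween(segs[[1]], segs[[2]], ra, rb, maxLag)
      res$xcorr <- list(
        maxLag = maxLag,
        withinMatrix = within, betweenMatrix = between,
        withinSummary = connectivitySummary(within),
        betweenSummary = connectivitySummary(between, within = FALSE))
    }
  }
  if (!is.null(outDir)) writePipelineOutputs(res, outDir)
  res
}

# write every stage's tables under outDir as delimited text / JSON
writePipelineOutputs <- function(res, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeConfig(res$config, file.path(outDir, "config.yaml"))
  utils::write.csv(res$graphStats, file.path(outDir, "graph_stats.csv"),
                   row.names = FALSE)
  edges <- which(adjacencyMatrix(res$graph) == 1, arr.ind = TRUE)
  edges <- edges[edges[, 1] < edges[, 2], , drop = FALSE]
  ids <- cellIds(res$graph)
  utils::write.table(
    data.frame(a = ids[edges[, 1]], b = ids[edges[, 2]]),
    file.path(outDir, "edges.tsv"), sep = "\t", row.names = FALSE)
  utils::write.csv(cellGeometry(res$graph),
                   file.path(outDir, "geometry.csv"), row.names = FALSE)
  for (ag in names(res$perAgonist)) {
    pa <- res$perAgonist[[ag]]
    utils::write.csv(pa$events,
                     file.path(outDir, paste0("events_", ag, ".csv")),
                     row.names = FALSE)
    utils::write.csv(pa$summaries,
                     file.path(outDir, paste0("summaries_", ag, ".csv")),
                     row.names = FALSE)
    if (!is.null(pa$partition))
      jsonlite::write_json(
        list(communities = pa$partition$communities,
             isolated = pa$partition$isolated),
        file.path(outDir, paste0("communities_", ag, ".json")))
    if (!is.null(pa$influence))
      utils::write.csv(pa$influence$curve$curve,
                       file.path(outDir,
                                 paste0("influence_curve_", ag, ".csv")),
                       row.names = FALSE)
  }
  if (!is.null(res$centrality))
    utils::write.csv(res$centrality,
                     file.path(outDir, "centrality.csv"),
                     row.names = FALSE)
  if (!is.null(res$xcorr)) {
    utils::write.csv(res$xcorr$withinSummary,
                     file.path(outDir, "xcorr_within.csv"),
                     row.names = FALSE)
    utils::write.csv(res$xcorr$betweenSummary,
                     file.path(outDir, "xcorr_between.csv"),
                     row.names = FALSE)
  }
  invisible(outDir)
}
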