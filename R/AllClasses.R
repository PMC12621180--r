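#' @import methods
NULL

#' TraceSet: per-cell F/F0 fluorescence time series
#'
#' Container for a matrix of fluorescence traces sampled on a uniform time
#' grid, one column per cell. Values are fractional fluorescence (F/F0) so a
#' resting cell sits near 1. An optional stimulus onset marks the start of
#' agonist exposure; analyses that need a pre-stimulus baseline (e.g.
#' \code{\link{detectBaseline}}) use it to restrict their search.
#'
#' @slot values numeric matrix, frames x cells; column names are cell ids.
#' @slot frameRate sampling rate in Hz.
#' @slot stimulusOnset stimulus onset in seconds, or \code{NA} if none.
#'
#' @exportClass TraceSet
setClass("TraceSet",
  representation(
    values = "matrix",
    frameRate = "numeric",
    stimulusOnset = "numeric"
  )
)

setValidity("TraceSet", function(object) {
  msgs <- character()
  if (!is.numeric(object@values)) msgs <- c(msgs, "values must be numeric")
  if (anyNA(object@values) || any(!is.finite(object@values)))
    msgs <- c(msgs, "values must be finite")
  if (length(object@frameRate) != 1L || object@frameRate <= 0)
    msgs <- c(msgs, "frameRate must be a single positive number")
  if (is.null(colnames(object@values)))
    msgs <- c(msgs, "values must have column names (cell ids)")
  if (length(object@stimulusOnset) != 1L)
    msgs <- c(msgs, "stimulusOnset must be length 1 (possibly NA)")
  if (length(msgs)) msgs else TRUE
})

#' Construct a TraceSet
#'
#' @param values frames x cells numeric matrix of F/F0 values.
#' @param frameRate sampling rate (Hz).
#' @param stimulusOnset stimulus onset time (s) or \code{NA}.
#' @param cellIds optional cell identifiers; defaults to existing column
#'   names, else \code{1:ncol}.
#' @return A \linkS4class{TraceSet}.
#' @export
TraceSet <- function(values, frameRate, stimulusOnset = NA_real_,
                     cellIds = NULL) {
  values <- as.matrix(values)
  if (!is.null(cellIds)) {
    colnames(values) <- as.character(cellIds)
  } else if (is.null(colnames(values))) {
    colnames(values) <- as.character(seq_len(ncol(values)))
  }
  new("TraceSet", values = values, frameRate = as.numeric(frameRate),
      stimulusOnset = as.numeric(stimulusOnset))
}

#' TissueGraph: structural cell-adjacency network
#'
#' Undirected, unweighted adjacency between cells derived from a labelled
#' mask: background pixels are assigned to the nearest label (generalized
#' Voronoi expansion) and two cells are neighbours when their expanded
#' regions share enough four-connected pixel contacts. Boundary cells (on
#' the concave hull of the field of view or touching the image frame) are
#' flagged; all downstream analyses use interior cells only.
#'
#' @slot adjacency symmetric 0/1 matrix with zero diagonal; dimnames are
#'   cell ids.
#' @slot boundary named logical vector, TRUE for boundary cells.
#' @slot geometry data.frame with one row per cell: \code{cell_id},
#'   \code{centroid_x}, \code{centroid_y}, \code{area},
#'   \code{aspect_ratio}, \code{frame_touching}.
#'
#' @exportClass TissueGraph
setClass("TissueGraph",
  representation(
    adjacency = "matrix",
    boundary = "logical",
    geometry = "data.frame"
  )
)

setValidity("TissueGraph", function(object) {
  A <- object@adjacency
  msgs <- character()
  if (nrow(A) != ncol(A)) msgs <- c(msgs, "adjacency must be square")
  if (nrow(A) > 0) {
    if (!isTRUE(all.equal(A, t(A)))) msgs <- c(msgs, "adjacency must be symmetric")
    if (any(diag(A) != 0)) msgs <- c(msgs, "adjacency diagonal must be zero")
    if (!all(A %in% c(0, 1))) msgs <- c(msgs, "adjacency must be 0/1")
    if (is.null(rownames(A))) msgs <- c(msgs, "adjacency must carry cell ids")
  }
  if (length(object@boundary) != nrow(A))
    msgs <- c(msgs, "boundary flags must match node count")
  if (length(msgs)) msgs else TRUE
})

#' SimulationConfig: parameters of the synthetic tissue generator
#'
#' Defines a synthetic endothelial sheet (tessellation), the spatial layout
#' of agonist-sensitive cells, and the stochastic Ca2+ transient model. The
#' per-cell event hazard at frame time t is
#' \deqn{\lambda_i(t) = base + s_i r(C) (1 + \beta k_i(t))}
#' where \eqn{s_i} indicates sensitivity to the applied agonist, \eqn{r(C)}
#' is the concentration-dependent drive, and \eqn{k_i(t)} counts neighbours
#' with an event onset within the coupling window. In venous mode \eqn{r(C)}
#' follows a 4-parameter logistic (frequency encoding, fixed amplitude
#' distribution); in arterial mode the event amplitude follows the 4PL and
#' the rate follows a bell curve on log-concentration.
#'
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    nCells = "numeric",
    elongation = "numeric",
    gridJitter = "numeric",
    imageSize = "numeric",
    frameRate = "numeric",
    duration = "numeric",
    stimulusOnset = "numeric",
    noiseSd = "numeric",
    baseRate = "numeric",
    driveMode = "character",
    driveParams = "list",
    couplingBeta = "numeric",
    couplingWindow = "numeric",
    refractory = "numeric",
    communitySeeds = "numeric",
    growthProb = "numeric",
    sensitiveFrac = "numeric",
    overlapFrac = "numeric",
    bridgePlacement = "logical",
    eventShape = "list",
    rngSeed = "numeric"
  )
)

setValidity("SimulationConfig", function(object) {
  msgs <- character()
  if (object@nCells < 4) msgs <- c(msgs, "nCells must be >= 4")
  if (object@elongation < 1) msgs <- c(msgs, "elongation must be >= 1")
  if (object@overlapFrac < 0 || object@overlapFrac >= 1)
    msgs <- c(msgs, "overlapFrac must be in [0, 1)")
  if (object@noiseSd < 0) msgs <- c(msgs, "noiseSd must be >= 0")
  if (object@couplingBeta < 0) msgs <- c(msgs, "couplingBeta must be >= 0")
  if (object@baseRate < 0) msgs <- c(msgs, "baseRate must be >= 0")
  if (object@frameRate <= 0) msgs <- c(msgs, "frameRate must be > 0")
  if (object@duration <= 0) msgs <- c(msgs, "duration must be > 0")
  if (!object@driveMode %in% c("venous", "arterial"))
    msgs <- c(msgs, "driveMode must be 'venous' or 'arterial'")
  if (object@growthProb <= 0 || object@growthProb > 1)
    msgs <- c(msgs, "growthProb must be in (0, 1]")
  if (object@stimulusOnset < 15)
    msgs <- c(msgs, "stimulusOnset must be >= 15 s (baseline search region)")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SimulationConfig
#'
#' Defaults describe a venous (polygonal, frequency-encoded) sheet imaged at
#' 10 Hz with an F/F0 noise SD of 0.05 and clustered agonist sensitivity.
#' Switch \code{driveMode = "arterial"} (with \code{elongation} around 3)
#' for an elongated, amplitude-encoded sheet.
#'
#' @param nCells number of cells in the tessellation.
#' @param elongation length/width scale of the lattice (1 = polygonal
#'   venous, ~3 = elongated arterial).
#' @param gridJitter seed jitter as a fraction of the lattice pitch.
#' @param imageSize rendered mask size in pixels (square).
#' @param frameRate sampling rate (Hz).
#' @param duration recording length (s).
#' @param stimulusOnset agonist onset (s); at least 15 s so the 10-s
#'   baseline search always has a pre-stimulus region.
#' @param noiseSd white-noise SD on the F/F0 baseline.
#' @param baseRate spontaneous event rate (events/s) for every cell.
#' @param driveMode \code{"venous"} (rate follows a 4PL of concentration,
#'   amplitudes fixed) or \code{"arterial"} (amplitude follows the 4PL,
#'   rate follows a bell curve).
#' @param driveParams list of drive-curve parameters; see Details.
#' @param couplingBeta hazard multiplier per recently active neighbour.
#' @param couplingWindow seconds over which a neighbour onset counts as
#'   recent activity.
#' @param refractory per-cell dead time (s) after an onset during which the
#'   hazard is zero; transients closer than the rise + peak time are not
#'   physiologically distinct (store depletion) nor resolvable.
#' @param communitySeeds number of seeded sensitivity communities per
#'   agonist.
#' @param growthProb probability of recruiting a neighbour into a growing
#'   sensitivity community.
#' @param sensitiveFrac fraction of interior cells sensitive to each
#'   agonist.
#' @param overlapFrac fraction of interior cells that are multisensitive.
#' @param bridgePlacement place multisensitive cells preferentially at
#'   positions adjacent to both sensitivity communities; disable for null
#'   experiments.
#' @param eventShape list of EMG transient shape parameters: means/SDs of
#'   sigma and tau (s), the amplitude coefficient of variation
#'   \code{ampSd}, the venous-mode mean amplitude \code{ampMean} (F/F0)
#'   and the absolute amplitude floor \code{ampFloor}.
#' @param rngSeed integer seed; identical configs give bit-identical
#'   outputs.
#'
#' @details \code{driveParams} fields: \code{rateBottom}, \code{rateTop},
#' \code{rateLogEC50}, \code{rateHill} (venous rate 4PL);
#' \code{ampBottom}, \code{ampTop}, \code{ampLogEC50}, \code{ampHill}
#' (arterial amplitude 4PL); \code{bellBase}, \code{bellHeight},
#' \code{bellCenter}, \code{bellWidth} (arterial rate bell). Concentrations
#' are molar; curves are evaluated on log10 concentration.
#'
#' @return A \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(nCells = 200,
                             elongation = 1,
                             gridJitter = 0.25,
                             imageSize = 512,
                             frameRate = 10,
                             duration = 600,
                             stimulusOnset = 20,
                             noiseSd = 0.05,
                             baseRate = 0.001,
                             driveMode = c("venous", "arterial"),
                             driveParams = list(),
                             couplingBeta = 0.25,
                             couplingWindow = 6,
                             refractory = 2.5,
                             communitySeeds = 2,
                             growthProb = 0.8,
                             sensitiveFrac = 0.17,
                             overlapFrac = 0.05,
                             bridgePlacement = TRUE,
                             eventShape = list(),
                             rngSeed = 1L) {
  driveMode <- match.arg(driveMode)
  dp <- list(
    rateBottom = 0.004, rateTop = 0.04, rateLogEC50 = -6.5, rateHill = 1,
    ampBottom = 0.6, ampTop = 2, ampLogEC50 = -6.5, ampHill = 1,
    bellBase = 0.04, bellHeight = 0.005, bellCenter = -6.5, bellWidth = 0.7
  )
  dp[names(driveParams)] <- driveParams
  es <- list(sigmaMean = 0.5, sigmaSd = 0.1, tauMean = 1.5, tauSd = 0.3,
             ampMean = 1.0, ampSd = 0.25, ampFloor = 0.1)
  es[names(eventShape)] <- eventShape
  new("SimulationConfig", nCells = nCells, elongation = elongation,
      gridJitter = gridJitter, imageSize = imageSize, frameRate = frameRate,
      duration = duration, stimulusOnset = stimulusOnset, noiseSd = noiseSd,
      baseRate = baseRate, driveMode = driveMode, driveParams = dp,
      couplingBeta = couplingBeta, couplingWindow = couplingWindow,
      refractory = refractory, communitySeeds = communitySeeds, growthProb = growthProb,
      sensitiveFrac = sensitiveFrac, overlapFrac = overlapFrac,
      bridgePlacement = bridgePlacement, eventShape = es,
      rngSeed = rngSeed)
}
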