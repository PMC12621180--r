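#' Align datasets on activity onset and cut comparable segments
#'
#' Each dataset's segment starts \code{baselineSpan} seconds before its
#' activity onset (the configured stimulus onset when available, otherwise
#' the supplied onset, e.g. the first detected event) and all segments are
#' truncated to the shortest combined baseline + activity duration across
#' the compared datasets.
#'
#' @param traceList list of \linkS4class{TraceSet} objects.
#' @param onsets activity onset (s) per dataset; defaults to each
#'   dataset's stimulus onset.
#' @param baselineSpan pre-onset baseline (s) to include.
#' @return list of \linkS4class{TraceSet} segments of equal duration.
#' @export
alignAndWindow <- function(traceList, onsets = NULL, baselineSpan = 10) {
  if (is.null(onsets))
    onsets <- vapply(traceList, stimulusOnset, numeric(1))
  if (any(is.na(onsets)))
    stop("missing activity onset for at least one dataset")
  stopifnot(length(onsets) == length(traceList))
  durs <- mapply(function(ts, on) {
    if (on < baselineSpan)
      stop("dataset has less than ", baselineSpan, " s before onset")
    nrow(traceMatrix(ts)) / frameRate(ts) - on
  }, traceList, onsets)
  common <- baselineSpan + min(durs)
  mapply(function(ts, on) {
    fr <- frameRate(ts)
    a <- round((on - baselineSpan) * fr) + 1L
    b <- min(nrow(traceMatrix(ts)), a + round(common * fr) - 1L)
    TraceSet(traceMatrix(ts)[a:b, , drop = FALSE], fr,
             stimulusOnset = baselineSpan)
  }, traceList, onsets, SIMPLIFY = FALSE)
}

# Pearson correlation of two equal-length demeaned halves at a given
# integer shift, computed on the overlapping support.
corAtLag <- function(x, y, lag) {
  n <- length(x)
  if (lag >= 0) { xi <- seq_len(n - lag); yi <- xi + lag }
  else { yi <- seq_len(n + lag); xi <- yi - lag }
  if (length(xi) < 3) return(NA_real_)
  sx <- stats::sd(x[xi]); sy <- stats::sd(y[yi])
  if (sx == 0 || sy == 0) return(NA_real_)
  stats::cor(x[xi], y[yi])
}

#' Lagged, segmented cross-correlation coefficient for one signal pair
#'
#' The equal-length signals are split into two halves (early and late
#' phase). Within each half both signals are demeaned, the normalized
#' cross-correlation is evaluated at every integer-frame shift within
#' \code{[-maxLag, +maxLag]} on the overlapping support, and the maximum
#' is taken, floored at 0. The reported coefficient is the median of the
#' two half values (equal to their mean for two values), so it lies in
#' [0, 1]. A zero-variance half contributes 0 with a flag.
#'
#' @param x,y numeric vectors of equal length.
#' @param maxLagFrames maximum shift in frames.
#' @return list: coefficient, halves (the two half maxima), flat (TRUE if
#'   a half had zero variance).
#' @export
xcorrPair <- function(x, y, maxLagFrames) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 2 * maxLagFrames)
  half <- floor(n / 2)
  parts <- list(seq_len(half), (half + 1L):n)
  flat <- FALSE
  vals <- vapply(parts, function(idx) {
    xs <- x[idx] - mean(x[idx])
    ys <- y[idx] - mean(y[idx])
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0) {
      flat <<- TRUE
      return(0)
    }
    cc <- vapply(-maxLagFrames:maxLagFrames,
                 function(l) corAtLag(xs, ys, l), numeric(1))
    max(0, max(cc, na.rm = TRUE))
  }, numeric(1))
  list(coefficient = mean(vals), halves = vals, flat = flat)
}

#' Pairwise cross-correlation matrix
#'
#' @param traces a \linkS4class{TraceSet} segment (already aligned).
#' @param cells cell ids to compare (default all).
#' @param maxLag maximum shift in seconds (three times the median event
#'   FDHM in the standard pipeline).
#' @return symmetric matrix of coefficients in [0, 1], unit diagonal.
#' @export
xcorrMatrix <- function(traces, cells = NULL, maxLag) {
  vals <- traceMatrix(traces)
  if (is.null(cells)) cells <- colnames(vals)
  cells <- as.character(cells)
  L <- round(maxLag * frameRate(traces))
  m <- matrix(1, length(cells), length(cells),
              dimnames = list(cells, cells))
  if (length(cells) < 2) return(m)
  for (i in seq_len(length(cells) - 1)) for (j in (i + 1):length(cells)) {
    cc <- xcorrPair(vals[, cells[i]], vals[, cells[j]], L)$coefficient
    m[i, j] <- cc
    m[j, i] <- cc
  }
  m
}

#' Cross-correlation between cells of two aligned datasets
#'
#' Correlates each cell of \code{tracesA} with each cell of
#' \code{tracesB} (equal-length aligned segments), e.g. agonist-A
#' responders in their own recording versus agonist-B responders in
#' theirs.
#'
#' @param tracesA,tracesB aligned \linkS4class{TraceSet} segments.
#' @param cellsA,cellsB cell ids to compare.
#' @param maxLag maximum shift in seconds.
#' @return matrix (cellsA x cellsB) of coefficients.
#' @export
xcorrBetween <- function(tracesA, tracesB, cellsA, cellsB, maxLag) {
  va <- traceMatrix(tracesA); vb <- traceMatrix(tracesB)
  stopifnot(nrow(va) == nrow(vb))
  L <- round(maxLag * frameRate(tracesA))
  m <- matrix(NA_real_, length(cellsA), length(cellsB),
              dimnames = list(cellsA, cellsB))
  for (i in seq_along(cellsA)) for (j in seq_along(cellsB))
    m[i, j] <- xcorrPair(va[, cellsA[i]], vb[, cellsB[j]], L)$coefficient
  m
}

#' Per-node 75th-percentile connectivity summary
#'
#' For each node of the reference set, the 75th percentile (linear
#' interpolation between order statistics) of its coefficients to the
#' comparison set, self-pairs excluded. With one matrix this is the
#' within-set summary; with a rectangular between-set matrix the
#' comparison set is its columns.
#'
#' @param coefMatrix square within-set matrix, or rectangular
#'   reference x comparison matrix.
#' @param within TRUE when \code{coefMatrix} is square and self-pairs
#'   must be dropped.
#' @return data.frame: cell_id, q75.
#' @export
connectivitySummary <- function(coefMatrix, within = NULL) {
  if (is.null(within))
    within <- nrow(coefMatrix) == ncol(coefMatrix) &&
      identical(rownames(coefMatrix), colnames(coefMatrix))
  if (ncol(coefMatrix) - as.integer(within) < 1)
    stop("comparison set must contain at least one other node")
  out <- do.call(rbind, lapply(seq_len(nrow(coefMatrix)), function(i) {
    v <- coefMatrix[i, ]
    if (within) v <- v[-i]
    data.frame(cell_id = rownames(coefMatrix)[i],
               q75 = unname(stats::quantile(v, 0.75, type = 7)))
  }))
  rownames(out) <- NULL
  out
}
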