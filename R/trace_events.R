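#' Savitzky-Golay smoothing of a fluorescence trace
#'
#' 21-point, third-order Savitzky-Golay filter (defaults). Edge samples are
#' smoothed by evaluating the polynomial fitted to the terminal window, so
#' polynomials up to the filter order are reproduced everywhere.
#'
#' @param x numeric vector of per-frame values.
#' @param window filter window length (odd).
#' @param order polynomial order.
#' @return smoothed vector of the same length.
#' @export
smoothTrace <- function(x, window = 21, order = 3) {
  if (length(x) < window)
    stop("trace shorter than the smoothing window (", window, " frames)")
  as.numeric(signal::sgolayfilt(x, p = order, n = window))
}

#' Locate the quietest 10-s baseline window
#'
#' Slides a window of \code{span} seconds one frame at a time over the
#' smoothed trace (restricted to end before \code{stimulusOnset} when one
#' is given) and returns the window with the lowest standard deviation,
#' taking the earliest window on ties. "Activity" is operationalized as
#' the window SD of the smoothed trace.
#'
#' @param x smoothed trace values.
#' @param frameRate sampling rate (Hz).
#' @param stimulusOnset stimulus onset (s) or NA.
#' @param span baseline window length (s).
#' @return list with \code{start}, \code{end} (s), \code{startFrame},
#'   \code{endFrame}, \code{mean}, \code{sd}.
#' @export
detectBaseline <- function(x, frameRate, stimulusOnset = NA, span = 10) {
  w <- round(span * frameRate)
  limit <- length(x)
  if (!is.na(stimulusOnset))
    limit <- min(limit, floor(stimulusOnset * frameRate))
  if (limit < w)
    stop("insufficient pre-stimulus data for a ", span, "-s baseline")
  st <- slidingStats(x[seq_len(limit)], w)
  i <- which.min(st$sd)  # earliest window on ties
  list(start = (i - 1) / frameRate, end = (i - 1 + w) / frameRate,
       startFrame = i, endFrame = i + w - 1L,
       mean = st$mean[i], sd = st$sd[i])
}

#' Detect suprathreshold event segments
#'
#' Candidate events are contiguous runs where the smoothed trace exceeds
#' the baseline mean by \code{threshold} baseline SDs. Runs separated by
#' less than \code{mergeGap} seconds below threshold are merged; within a
#' run, an additional event is split at any local minimum that drops below
#' half of the smaller adjacent peak's height above the threshold level.
#'
#' @param x smoothed trace values.
#' @param baseline result of \code{\link{detectBaseline}}.
#' @param frameRate sampling rate (Hz).
#' @param threshold threshold in baseline SD multiples.
#' @param mergeGap sub-threshold gap (s) below which runs merge.
#' @return data.frame of segments: startFrame, endFrame, peakFrame.
#' @export
detectEventSegments <- function(x, baseline, frameRate, threshold = 5,
                                mergeGap = 0.5) {
  sdFloor <- max(baseline$sd, .Machine$double.eps)
  level <- baseline$mean + threshold * sdFloor
  above <- x > level
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  if (nrow(runs) == 0L)
    return(data.frame(startFrame = integer(), endFrame = integer(),
                      peakFrame = integer()))
  gapFrames <- round(mergeGap * frameRate)
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) for (i in 2:nrow(runs)) {
    if (runs[i, 1] - merged[nrow(merged), 2] - 1L < gapFrames)
      merged[nrow(merged), 2] <- runs[i, 2]
    else merged <- rbind(merged, runs[i, ])
  }
  segs <- list()
  for (i in seq_len(nrow(merged))) {
    segs <- c(segs, splitRun(x, merged[i, 1], merged[i, 2], level,
                             minHeight = 3 * sdFloor))
  }
  out <- do.call(rbind, lapply(segs, function(s) {
    pk <- s[1] - 1L + which.max(x[s[1]:s[2]])
    data.frame(startFrame = s[1], endFrame = s[2], peakFrame = pk)
  }))
  rownames(out) <- NULL
  out
}

# split a suprathreshold run at qualifying local minima (50% prominence
# relative to the smaller adjacent peak's height above threshold); local
# maxima must clear the threshold level by minHeight to count as peaks,
# which keeps noise ripples on decay tails from fragmenting an event
splitRun <- function(x, a, b, level, minHeight = 0) {
  seg <- x[a:b]
  n <- length(seg)
  if (n < 3) return(list(c(a, b)))
  isMax <- c(FALSE, seg[2:(n - 1)] > seg[1:(n - 2)] &
               seg[2:(n - 1)] >= seg[3:n], FALSE)
  peaks <- which(isMax & seg - level >= minHeight)
  if (length(peaks) < 2) return(list(c(a, b)))
  cuts <- integer(0)
  for (i in seq_len(length(peaks) - 1)) {
    lo <- peaks[i]; hi <- peaks[i + 1]
    m <- lo - 1L + which.min(seg[lo:hi])
    hMin <- min(seg[lo], seg[hi]) - level
    if (seg[m] - level < 0.5 * hMin) cuts <- c(cuts, m)
  }
  if (length(cuts) == 0) return(list(c(a, b)))
  bounds <- c(a - 1L, a - 1L + cuts, b)
  lapply(seq_len(length(bounds) - 1),
         function(i) c(bounds[i] + 1L, bounds[i + 1]))
}

# fractional-level metrics (rise 10-90%, fall 90-10%, width at half max)
# measured on a curve sampled at times tg, relative to baseline mean;
# peakIndex anchors the measurement on a specific peak (default global max)
measureShape <- function(tg, y, blMean, peakIndex = NULL) {
  ip <- if (is.null(peakIndex)) which.max(y) else peakIndex
  amp <- y[ip] - blMean
  lvl <- function(frac) blMean + frac * amp
  crossUp <- function(level) {
    # last upward crossing before the anchored peak
    ix <- which(y[seq_len(ip)] < level)
    if (length(ix) == 0) return(tg[1])
    i <- ix[length(ix)] + 1L
    if (i > ip) return(tg[ip])
    tg[i - 1] + (level - y[i - 1]) / (y[i] - y[i - 1]) * (tg[i] - tg[i - 1])
  }
  crossDown <- function(level) {
    tail <- y[ip:length(y)]
    ix <- which(tail <= level)
    if (length(ix) == 0) return(tg[length(tg)])
    i <- ix[1] + ip - 1L
    if (i == ip) return(tg[ip])
    tg[i - 1] + (level - y[i - 1]) / (y[i] - y[i - 1]) * (tg[i] - tg[i - 1])
  }
  list(peak_time = tg[ip], amplitude = amp,
       rise_time = crossUp(lvl(0.9)) - crossUp(lvl(0.1)),
       fall_time = crossDown(lvl(0.1)) - crossDown(lvl(0.9)),
       fdhm = crossDown(lvl(0.5)) - crossUp(lvl(0.5)))
}

#' Fit an exponentially modified Gaussian to one event
#'
#' Least-squares EMG fit over the segment extended by 3 s on each side,
#' initialized from the segment shape. Rise time (10->90%), fall time
#' (90->10%) and FDHM are measured on the fitted curve and then re-measured
#' at the same fractional levels on the smoothed real signal, which is what
#' the returned values report (fitted parameters are kept in
#' \code{mu/sigma/tau/area}). Segments shorter than 5 frames, or fits that
#' fail to converge, fall back to the empirical threshold-crossing metrics
#' with \code{fit_ok = FALSE}; no exception is thrown.
#'
#' @param segment one row of \code{\link{detectEventSegments}} output.
#' @param x smoothed trace values.
#' @param baseline result of \code{\link{detectBaseline}}.
#' @param frameRate sampling rate (Hz).
#' @param raw the raw normalized trace; the EMG is fitted to it (smoothing
#'   broadens sharp transients, so fitting the smoothed trace would bias
#'   sigma upward), while fractional-level metrics are re-measured on the
#'   smoothed signal. Defaults to \code{x}.
#' @return one-row data.frame: peak_time, amplitude, rise_time, fall_time,
#'   fdhm, fit_ok, mu, sigma, tau, area.
#' @export
fitEvent <- function(segment, x, baseline, frameRate, raw = x) {
  ext <- round(3 * frameRate)
  lo <- max(1L, segment$startFrame - ext)
  hi <- min(length(x), segment$endFrame + ext)
  tg <- (seq(lo, hi) - 1) / frameRate
  y <- raw[lo:hi] - baseline$mean
  tPeak <- (segment$peakFrame - 1) / frameRate
  hPeak <- x[segment$peakFrame] - baseline$mean
  nFrames <- segment$endFrame - segment$startFrame + 1L
  anchor <- segment$peakFrame - lo + 1L
  empirical <- function() {
    m <- measureShape(tg, x[lo:hi], baseline$mean, peakIndex = anchor)
    data.frame(peak_time = m$peak_time, amplitude = m$amplitude,
               rise_time = m$rise_time, fall_time = m$fall_time,
               fdhm = m$fdhm, fit_ok = FALSE,
               mu = NA_real_, sigma = NA_real_, tau = NA_real_,
               area = NA_real_,
               fit_rise = NA_real_, fit_fall = NA_real_,
               fit_fdhm = NA_real_, fit_amplitude = NA_real_,
               fit_peak_time = NA_real_)
  }
  if (nFrames < 5) return(empirical())
  width <- nFrames / frameRate
  # tau init: time from peak to 1/e decay on the real signal
  tail <- x[segment$peakFrame:hi] - baseline$mean
  below <- which(tail <= hPeak / exp(1))
  tau0 <- if (length(below)) max(below[1] - 1, 1) / frameRate else width / 2
  sigma0 <- max(width / 4, 1 / frameRate)
  shape0 <- emgShape(tg, tPeak, sigma0, tau0)
  k0 <- hPeak / max(shape0, 1e-12)
  start <- list(k = k0, mu = tPeak, sigma = sigma0, tau = tau0)
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      y ~ k * emgShape(tg, mu, sigma, tau),
      start = start,
      lower = c(k = 0, mu = tg[1] - 5, sigma = 1e-3, tau = 1e-4),
      upper = c(k = Inf, mu = tg[length(tg)] + 5, sigma = 60, tau = 120),
      control = minpack.lm::nls.lm.control(maxiter = 100)
    )),
    error = function(e) NULL
  )
  if (is.null(fit)) return(empirical())
  p <- as.list(stats::coef(fit))
  if (!all(is.finite(unlist(p))) || p$k <= 0) return(empirical())
  # dense evaluation of the fitted transient for fractional-level metrics
  dtF <- min(p$sigma, p$tau, 1 / frameRate) / 4
  tf <- seq(p$mu - 6 * p$sigma, p$mu + 8 * p$tau + 6 * p$sigma, by = dtF)
  yf <- p$k * emgShape(tf, p$mu, p$sigma, p$tau)
  if (max(yf) <= 0 || !all(is.finite(yf))) return(empirical())
  mf <- measureShape(tf, yf, 0)
  # translate to the real signal: same fractional levels on the smoothed
  # trace around the detected peak
  mr <- measureShape(tg, x[lo:hi], baseline$mean, peakIndex = anchor)
  data.frame(peak_time = mr$peak_time, amplitude = mr$amplitude,
             rise_time = mr$rise_time, fall_time = mr$fall_time,
             fdhm = mr$fdhm, fit_ok = TRUE,
             mu = p$mu, sigma = p$sigma, tau = p$tau,
             area = p$k,
             fit_rise = mf$rise_time, fit_fall = mf$fall_time,
             fit_fdhm = mf$fdhm, fit_amplitude = mf$amplitude,
             fit_peak_time = mf$peak_time)
}

#' Detect and parameterize Ca2+ events in every cell of a TraceSet
#'
#' Runs the full per-cell chain: normalize to the baseline-window mean of
#' the raw trace (F0), smooth, locate the quietest baseline, threshold at
#' \code{threshold} baseline SDs, merge/split candidate runs, and fit an
#' EMG to each event.
#'
#' @param traces a \linkS4class{TraceSet}.
#' @param threshold detection threshold in baseline SD multiples.
#' @param span baseline window length (s).
#' @param window,order Savitzky-Golay parameters.
#' @param mergeGap sub-threshold merge gap (s).
#' @param fit if FALSE skip EMG fitting and report empirical metrics
#'   (fit_ok = FALSE throughout).
#' @return event table with one row per event (cell_id, peak_time,
#'   amplitude, rise_time, fall_time, fdhm, fit_ok, mu, sigma, tau, area).
#' @export
detectEvents <- function(traces, threshold = 5, span = 10,
                         window = 21, order = 3, mergeGap = 0.5,
                         fit = TRUE) {
  vals <- traceMatrix(traces)
  fr <- frameRate(traces)
  onset <- stimulusOnset(traces)
  out <- lapply(colnames(vals), function(id) {
    raw <- vals[, id]
    sm0 <- smoothTrace(raw, window, order)
    bl0 <- detectBaseline(sm0, fr, onset, span)
    f0 <- mean(raw[bl0$startFrame:bl0$endFrame])
    if (f0 <= 0) f0 <- 1
    sm <- smoothTrace(raw / f0, window, order)
    # threshold SD comes from the raw normalized trace in the selected
    # window: selecting the window by minimum smoothed SD biases the
    # smoothed SD low, which would turn the 5x multiple into ~2x
    bl <- list(start = bl0$start, end = bl0$end,
               startFrame = bl0$startFrame, endFrame = bl0$endFrame,
               mean = mean(sm[bl0$startFrame:bl0$endFrame]),
               sd = stats::sd(raw[bl0$startFrame:bl0$endFrame] / f0))
    segs <- detectEventSegments(sm, bl, fr, threshold, mergeGap)
    if (nrow(segs) == 0) return(NULL)
    ev <- do.call(rbind, lapply(seq_len(nrow(segs)), function(i) {
      if (fit) fitEvent(segs[i, ], sm, bl, fr, raw = raw / f0)
      else {
        lo <- segs$startFrame[i]; hi <- segs$endFrame[i]
        m <- measureShape((seq(lo, hi) - 1) / fr, sm[lo:hi], bl$mean)
        data.frame(peak_time = m$peak_time, amplitude = m$amplitude,
                   rise_time = m$rise_time, fall_time = m$fall_time,
                   fdhm = m$fdhm, fit_ok = FALSE, mu = NA_real_,
                   sigma = NA_real_, tau = NA_real_, area = NA_real_)
      }
    }))
    fill <- setdiff(c("fit_rise", "fit_fall", "fit_fdhm",
                      "fit_amplitude", "fit_peak_time"), names(ev))
    for (cn in fill) ev[[cn]] <- NA_real_
    cbind(data.frame(cell_id = id), ev)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(cell_id = character(), peak_time = numeric(),
                      amplitude = numeric(), rise_time = numeric(),
                      fall_time = numeric(), fdhm = numeric(),
                      fit_ok = logical(), mu = numeric(), sigma = numeric(),
                      tau = numeric(), area = numeric(),
                      fit_rise = numeric(), fit_fall = numeric(),
                      fit_fdhm = numeric(), fit_amplitude = numeric(),
                      fit_peak_time = numeric())
  rownames(out) <- NULL
  out
}

#' Per-cell activity summaries over the agonist-exposure interval
#'
#' Counts events with a peak inside the exposure interval and reports the
#' response frequency (events/min) that ranks cells for responder
#' selection, plus mean amplitude and median FDHM.
#'
#' @param events event table from \code{\link{detectEvents}}.
#' @param cellIds all cell ids to report (cells without events get zero
#'   frequency and NA amplitude).
#' @param exposure numeric length-2: start and end of the exposure
#'   interval (s).
#' @return data.frame: cell_id, event_count, frequency, mean_amplitude,
#'   median_fdhm.
#' @export
summarizeCells <- function(events, cellIds, exposure) {
  stopifnot(length(exposure) == 2, diff(exposure) > 0)
  minutes <- diff(exposure) / 60
  keep <- events$peak_time >= exposure[1] & events$peak_time <= exposure[2]
  ev <- events[keep, , drop = FALSE]
  out <- do.call(rbind, lapply(as.character(cellIds), function(id) {
    e <- ev[ev$cell_id == id, , drop = FALSE]
    data.frame(cell_id = id, event_count = nrow(e),
               frequency = nrow(e) / minutes,
               mean_amplitude = if (nrow(e)) mean(e$amplitude) else NA_real_,
               median_fdhm = if (nrow(e)) stats::median(e$fdhm) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}
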