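#' Fit a concentration-response curve
#'
#' Least-squares fit on log10 concentration. The sigmoid model is the
#' four-parameter logistic
#' \deqn{R = bottom + (top - bottom) / (1 + 10^{(logEC50 - logC) h})}
#' with EC25 derived from \eqn{log10 EC25 = log10 EC50 - log10(3)/h}; the
#' bell model is a log-Gaussian
#' \deqn{R = base + height \exp(-(logC - center)^2 / (2 width^2)).}
#'
#' @param concentrations molar concentrations (> 0).
#' @param responses response values (same length).
#' @param model "sigmoid" (4PL) or "bell".
#' @return list of class \code{doseResponseFit}: model, parameters,
#'   EC50/EC25 (sigmoid), fitted values, residual sum of squares,
#'   convergence flag.
#' @export
fitCurve <- function(concentrations, responses,
                     model = c("sigmoid", "bell")) {
  model <- match.arg(model)
  stopifnot(length(concentrations) == length(responses),
            length(concentrations) >= 4, all(concentrations > 0))
  logC <- log10(concentrations)
  df <- data.frame(logC = logC, r = responses)
  rMax <- max(abs(responses))
  if (model == "sigmoid") {
    start <- list(bottom = min(responses), top = max(responses),
                  logEC50 = stats::median(logC), h = 1)
    # box constraints keep the fitted span physical when the data are
    # nearly flat (responses are nonnegative rates/amplitudes and the
    # EC50 must lie near the tested range)
    plFit <- function(st) minpack.lm::nlsLM(
      r ~ fourPL(logC, bottom, top, logEC50, h),
      data = df, start = st,
      lower = c(bottom = 0, top = 0, logEC50 = min(logC) - 2, h = 0.1),
      upper = c(bottom = rMax, top = 2 * rMax,
                logEC50 = max(logC) + 2, h = 6),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    fit <- tryCatch(plFit(start), error = function(e) NULL)
    if (is.null(fit)) {
      start2 <- list(bottom = stats::median(responses),
                     top = stats::median(responses),
                     logEC50 = stats::median(logC), h = 1)
      fit <- tryCatch(plFit(start2),
                      error = function(e) stop("4PL fit failed: ",
                                               conditionMessage(e)))
    }
    p <- as.list(stats::coef(fit))
    if (p$h <= 0) warning("fitted hill slope is not positive")
    ec50 <- 10^p$logEC50
    ec25 <- 10^(p$logEC50 - log10(3) / p$h)
    out <- list(model = model, parameters = p, EC50 = ec50, EC25 = ec25,
                fitted = fourPL(logC, p$bottom, p$top, p$logEC50, p$h))
  } else {
    iMax <- which.max(responses)
    start <- list(base = min(responses),
                  height = max(responses) - min(responses),
                  center = logC[iMax],
                  width = max(diff(range(logC)) / 4, 0.5))
    bellFit <- function(st) minpack.lm::nlsLM(
      r ~ bellCurve(logC, base, height, center, width),
      data = df, start = st,
      lower = c(base = 0, height = 0,
                center = min(logC) - 1, width = 0.5),
      upper = c(base = rMax, height = 2 * rMax,
                center = max(logC) + 1, width = 4),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    fit <- tryCatch(bellFit(start), error = function(e) NULL)
    if (is.null(fit)) {
      start2 <- list(base = stats::median(responses), height = 0.1 * rMax,
                     center = stats::median(logC), width = 1)
      fit <- tryCatch(bellFit(start2),
                      error = function(e) stop("bell fit failed: ",
                                               conditionMessage(e)))
    }
    p <- as.list(stats::coef(fit))
    p$width <- abs(p$width)
    out <- list(model = model, parameters = p, EC50 = NA_real_,
                EC25 = NA_real_,
                fitted = bellCurve(logC, p$base, p$height, p$center,
                                   p$width))
  }
  out$rss <- sum((responses - out$fitted)^2)
  out$converged <- TRUE
  class(out) <- "doseResponseFit"
  out
}

#' @export
print.doseResponseFit <- function(x, ...) {
  cat("Dose-response fit (", x$model, ")\n", sep = "")
  print(unlist(x$parameters))
  if (x$model == "sigmoid")
    cat("EC50:", signif(x$EC50, 4), "M; EC25:", signif(x$EC25, 4), "M\n")
  cat("RSS:", signif(x$rss, 4), "\n")
  invisible(x)
}

# normalized dynamic range of a fitted curve: span of the fitted curve
# over the tested concentrations, relative to its maximum. Evaluating the
# realized curve (rather than raw top/bottom parameters) keeps the range
# meaningful when near-flat data leave the parameters ridge-degenerate
# (e.g. a very wide bell with base ~ 0).
dynamicRange <- function(fit, eps = 1e-12) {
  if (is.null(fit)) return(NA_real_)
  if (!is.null(fit$fitted) && length(fit$fitted) > 0) {
    top <- max(fit$fitted); bottom <- min(fit$fitted)
  } else {
    p <- fit$parameters
    if (fit$model == "sigmoid") {
      bottom <- min(p$bottom, p$top); top <- max(p$bottom, p$top)
    } else {
      bottom <- min(p$base, p$base + p$height)
      top <- max(p$base, p$base + p$height)
    }
  }
  (top - bottom) / max(top, eps)
}

#' Classify frequency- versus amplitude-encoding
#'
#' Compares the normalized dynamic range (span of the fitted curve over
#' its maximum) of the frequency and amplitude concentration-response
#' curves. The response is frequency-encoded when the frequency range
#' exceeds the amplitude range by at least \code{factor} (default 2),
#' amplitude-encoded in the reverse case, otherwise indeterminate.
#' Unfit (NULL) curves give an indeterminate verdict.
#'
#' @param freqFit,ampFit \code{doseResponseFit} objects (or NULL).
#' @param factor required fold difference between the two dynamic ranges.
#' @return list: label, freqRange, ampRange, factor.
#' @export
classifyEncoding <- function(freqFit, ampFit, factor = 2) {
  fr <- dynamicRange(freqFit)
  ar <- dynamicRange(ampFit)
  label <- if (is.na(fr) || is.na(ar)) "indeterminate"
  else if (fr >= factor * ar) "frequency-encoded"
  else if (ar >= factor * fr) "amplitude-encoded"
  else "indeterminate"
  list(label = label, freqRange = fr, ampRange = ar, factor = factor)
}

#' Responder overlap between two agonists
#'
#' Set algebra over the two responder sets: unisensitive counts (set
#' differences), multisensitive count (intersection) and the
#' multisensitive fraction of all interior cells.
#'
#' @param respondersA,respondersB responder cell ids.
#' @param nInterior number of interior cells.
#' @param labels agonist labels.
#' @return list: per-agonist unisensitive counts, nMultisensitive,
#'   multisensitiveFraction.
#' @export
overlapAnalysis <- function(respondersA, respondersB, nInterior,
                            labels = c("ACh", "BK")) {
  a <- unique(as.character(respondersA))
  b <- unique(as.character(respondersB))
  multi <- intersect(a, b)
  res <- list(length(setdiff(a, b)), length(setdiff(b, a)),
              nMultisensitive = length(multi),
              multisensitiveFraction = length(multi) / nInterior,
              multisensitive = multi)
  names(res)[1:2] <- paste0("nUnisensitive_", labels)
  res
}

#' Linear regression of a Ca2+ metric against relaxation
#'
#' Ordinary least squares of relaxation (%) on a per-concentration Ca2+
#' metric (e.g. event frequency), reporting slope, intercept and r^2.
#'
#' @param metric per-concentration Ca2+ metric values.
#' @param relaxation paired relaxation percentages.
#' @return list: slope, intercept, r2, n.
#' @export
metricRelaxationRegression <- function(metric, relaxation) {
  stopifnot(length(metric) == length(relaxation), length(metric) >= 3)
  if (stats::var(metric) == 0)
    stop("metric has zero variance; regression undefined")
  fit <- stats::lm(relaxation ~ metric)
  r2 <- if (stats::var(relaxation) > 0)
    stats::cor(metric, relaxation)^2 else NA_real_
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = r2,
       n = length(metric))
}
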