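#' Neighbour-influence analysis window
#'
#' The analysis window is three times the median FDHM of all detected
#' events (events whose EMG fit failed are excluded from the median).
#'
#' @param events event table from \code{\link{detectEvents}}.
#' @param multiple window multiple of the median FDHM (default 3).
#' @return window length in seconds.
#' @export
influenceWindow <- function(events, multiple = 3) {
  f <- events$fdhm[events$fit_ok & is.finite(events$fdhm)]
  if (length(f) == 0) stop("no events with a valid FDHM")
  multiple * stats::median(f)
}

#' Build case-control records of neighbour influence
#'
#' For every interior target cell: each target event at time t yields one
#' positive case with k = the number of distinct neighbours having an
#' event peak in [t - tw, t). Negative cases come from neighbour activity
#' not followed by a target response: neighbour events are sorted
#' chronologically and grouped into non-overlapping windows [t0, t0 + tw]
#' starting at the first ungrouped neighbour event (each neighbour counted
#' once per window); a group is a negative case iff the target has no
#' event peak inside that window. When a community partition is supplied,
#' each case is categorized as cluster (all case neighbours share the
#' target's community), non-cluster (none do) or mixed.
#'
#' @param events event table (peak_time-stamped).
#' @param graph a \linkS4class{TissueGraph}.
#' @param tw window length (s), from \code{\link{influenceWindow}}.
#' @param partition optional \code{\link{findCommunities}} result for the
#'   relevant agonist.
#' @return data.frame of cases: target, k, label ("positive"/"negative"),
#'   category ("cluster"/"non-cluster"/"mixed"/NA), ref_time, and for
#'   positive cases the target event's amplitude/rise/fall/fdhm.
#' @export
buildCases <- function(events, graph, tw, partition = NULL) {
  interior <- interiorCells(graph)
  A <- adjacencyMatrix(graph)
  commOf <- function(id) {
    if (is.null(partition)) return(NA_integer_)
    for (i in seq_along(partition$communities))
      if (id %in% partition$communities[[i]]) return(i)
    NA_integer_
  }
  cellF <- factor(as.character(events$cell_id), levels = colnames(A))
  idxByCell <- split(seq_len(nrow(events)), cellF)
  nbrList <- lapply(colnames(A), function(id) colnames(A)[A[id, ] > 0])
  names(nbrList) <- colnames(A)
  # accumulators (vectors, assembled into one frame at the end)
  tgt <- character(0)
  kk <- integer(0); lab <- cat_ <- character(0)
  rt <- amp <- ris <- fal <- fd <- numeric(0)
  push <- function(target, k, label, category, ref, a, r, f, d) {
    tgt[length(tgt) + 1L] <<- target
    kk[length(kk) + 1L] <<- k
    lab[length(lab) + 1L] <<- label
    cat_[length(cat_) + 1L] <<- category
    rt[length(rt) + 1L] <<- ref
    amp[length(amp) + 1L] <<- a
    ris[length(ris) + 1L] <<- r
    fal[length(fal) + 1L] <<- f
    fd[length(fd) + 1L] <<- d
  }
  for (target in interior) {
    nbrs <- nbrList[[target]]
    if (length(nbrs) == 0) next
    nIdx <- unlist(idxByCell[nbrs], use.names = FALSE)
    if (length(nIdx) == 0) next
    ntAll <- events$peak_time[nIdx]
    ncAll <- as.character(events$cell_id)[nIdx]
    ord <- order(ntAll)
    nt <- ntAll[ord]; ncs <- ncAll[ord]
    tIdx <- idxByCell[[target]]
    tTimes <- events$peak_time[tIdx]
    targetComm <- commOf(target)
    categorize <- function(cellIdsInCase) {
      if (is.null(partition)) return(NA_character_)
      if (is.na(targetComm)) return("non-cluster")
      inComm <- cellIdsInCase %in% partition$communities[[targetComm]]
      if (all(inComm)) "cluster"
      else if (!any(inComm)) "non-cluster"
      else "mixed"
    }
    # positive cases: one per target event with >= 1 recently active
    # distinct neighbour
    if (length(tTimes)) for (j in seq_along(tTimes)) {
      t0 <- tTimes[j]
      who <- unique(ncs[nt >= t0 - tw & nt < t0])
      if (length(who) == 0) next
      push(target, length(who), "positive", categorize(who), t0,
           events$amplitude[tIdx[j]], events$rise_time[tIdx[j]],
           events$fall_time[tIdx[j]], events$fdhm[tIdx[j]])
    }
    # negative cases: greedy non-overlapping windows over neighbour events
    i <- 1L
    while (i <= length(nt)) {
      t0 <- nt[i]
      who <- unique(ncs[nt >= t0 & nt <= t0 + tw])
      hasTarget <- any(tTimes >= t0 & tTimes <= t0 + tw)
      if (!hasTarget)
        push(target, length(who), "negative", categorize(who), t0,
             NA_real_, NA_real_, NA_real_, NA_real_)
      i <- which(nt > t0 + tw)[1]
      if (is.na(i)) break
    }
  }
  data.frame(target = tgt, k = kk, label = lab, category = cat_,
             ref_time = rt, amplitude = amp, rise_time = ris,
             fall_time = fal, fdhm = fd)
}

#' Event probability as a function of active-neighbour count
#'
#' P(event | k) = positives_k / (positives_k + negatives_k), with a linear
#' regression of P on k. When several case tables are aggregated, k is
#' restricted to values represented in every table.
#'
#' @param cases case table from \code{\link{buildCases}}, or a list of
#'   such tables from multiple datasets.
#' @param category optionally restrict to one neighbour category.
#' @return list with \code{curve} (data.frame k, positives, negatives, p),
#'   \code{slope}, \code{intercept}, \code{r2}.
#' @export
probabilityByK <- function(cases, category = NULL) {
  if (is.data.frame(cases)) cases <- list(cases)
  if (!is.null(category))
    cases <- lapply(cases, function(cs)
      cs[!is.na(cs$category) & cs$category == category, , drop = FALSE])
  kSets <- lapply(cases, function(cs) sort(unique(cs$k)))
  shared <- Reduce(intersect, kSets)
  all <- do.call(rbind, cases)
  all <- all[all$k %in% shared, , drop = FALSE]
  if (nrow(all) == 0)
    return(list(curve = data.frame(k = integer(), positives = integer(),
                                   negatives = integer(), p = numeric()),
                slope = NA_real_, intercept = NA_real_, r2 = NA_real_))
  ks <- sort(unique(all$k))
  curve <- do.call(rbind, lapply(ks, function(k) {
    sub <- all[all$k == k, ]
    pos <- sum(sub$label == "positive")
    neg <- sum(sub$label == "negative")
    data.frame(k = k, positives = pos, negatives = neg,
               p = pos / (pos + neg))
  }))
  curve <- curve[curve$positives + curve$negatives > 0, , drop = FALSE]
  if (nrow(curve) >= 2 && stats::var(curve$k) > 0) {
    fit <- stats::lm(p ~ k, data = curve)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
    r2 <- if (stats::var(curve$p) > 0)
      stats::cor(curve$k, curve$p)^2 else NA_real_
  } else {
    slope <- NA_real_; intercept <- NA_real_; r2 <- NA_real_
  }
  list(curve = curve, slope = slope, intercept = intercept, r2 = r2)
}

#' Event characteristics as a function of active-neighbour count
#'
#' Means of the target-event amplitude, rise time, fall time and FDHM of
#' positive cases, grouped by k (and by neighbour category when present).
#'
#' @param cases case table from \code{\link{buildCases}}.
#' @return data.frame: category, k, n, amplitude, rise_time, fall_time,
#'   fdhm.
#' @export
characteristicsByK <- function(cases) {
  pos <- cases[cases$label == "positive", , drop = FALSE]
  if (nrow(pos) == 0)
    return(data.frame(category = character(), k = integer(), n = integer(),
                      amplitude = numeric(), rise_time = numeric(),
                      fall_time = numeric(), fdhm = numeric()))
  pos$categoryGrp <- ifelse(is.na(pos$category), "all", pos$category)
  grp <- split(pos, list(pos$categoryGrp, pos$k), drop = TRUE)
  out <- do.call(rbind, lapply(grp, function(g)
    data.frame(category = g$categoryGrp[1], k = g$k[1], n = nrow(g),
               amplitude = mean(g$amplitude),
               rise_time = mean(g$rise_time),
               fall_time = mean(g$fall_time), fdhm = mean(g$fdhm))))
  out <- out[order(out$category, out$k), ]
  rownames(out) <- NULL
  out
}

#' Temporal permutation null for the neighbour-influence curve
#'
#' Randomly redistributes event timing across the network while holding
#' the number of events per cell constant: the pooled peak times are
#' shuffled and reassigned to events, so per-cell counts, the network
#' topology and community labels are untouched. Cases are rebuilt and
#' P(event | k) recomputed per permutation.
#'
#' @param events event table.
#' @param graph a \linkS4class{TissueGraph}.
#' @param tw window length (s).
#' @param nPerm number of permutations.
#' @param seed integer seed.
#' @param partition optional community partition (kept fixed).
#' @return list: observed probability curve, nullCurves (list of per-
#'   permutation curves), nullMeanByK (data.frame k, p), slopes (null
#'   slope distribution), slopeRecord (permutation-null record for the
#'   regression slope).
#' @export
temporalPermutationNull <- function(events, graph, tw, nPerm = 100,
                                    seed = 1, partition = NULL) {
  stopifnot(nrow(events) >= 1)
  obs <- probabilityByK(buildCases(events, graph, tw, partition))
  countsBefore <- table(events$cell_id)
  withSeed(seed, {
    nullCurves <- vector("list", nPerm)
    slopes <- numeric(nPerm)
    for (i in seq_len(nPerm)) {
      perm <- events
      perm$peak_time <- sample(perm$peak_time)
      stopifnot(identical(table(perm$cell_id), countsBefore))
      pc <- probabilityByK(buildCases(perm, graph, tw, partition))
      nullCurves[[i]] <- pc$curve
      slopes[i] <- pc$slope
    }
    ks <- sort(unique(unlist(lapply(nullCurves, function(cv) cv$k))))
    nullMeanByK <- do.call(rbind, lapply(ks, function(k) {
      ps <- unlist(lapply(nullCurves, function(cv) cv$p[cv$k == k]))
      data.frame(k = k, p = mean(ps), sd = stats::sd(ps), n = length(ps))
    }))
    list(observed = obs, nullCurves = nullCurves,
         nullMeanByK = nullMeanByK, slopes = slopes,
         slopeRecord = nullRecord("p_vs_k_slope", obs$slope,
                                  slopes[is.finite(slopes)]))
  })
}
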