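#' Generate a tessellated synthetic endothelial sheet
#'
#' Renders an integer label mask by Voronoi tessellation of a jittered
#' lattice. The lattice pitch along x is scaled by \code{elongation} before
#' tessellation, so cells elongate along x (arterial morphology) while
#' \code{elongation = 1} gives polygonal venous-like cells. Regions are
#' separated by 1-pixel background borders so downstream neighbour
#' detection exercises the expansion rule.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return list with \code{mask} (integer matrix, 0 = border background)
#'   and \code{geometry} (per-cell centroid, area, aspect ratio,
#'   frame-touching flag).
#' @export
generateTessellation <- function(config) {
  stopifnot(config@nCells >= 4)
  n <- as.integer(config@nCells)
  size <- as.integer(config@imageSize)
  for (attempt in 0:4) {
    seeds <- withSeed(deriveSeed(config@rngSeed, 11 + attempt),
                      tessellationSeeds(n, size, config@elongation,
                                        config@gridJitter))
    if (!anyDuplicated(round(seeds$xy, 6))) break
    if (attempt == 4) stop("coincident tessellation seeds after 5 attempts")
  }
  mask <- rasterizeVoronoi(seeds, size)
  list(mask = mask, geometry = maskGeometry(mask))
}

# jittered lattice seed positions; x pitch = elongation * y pitch
tessellationSeeds <- function(n, size, elongation, jitter) {
  ncc <- max(2L, ceiling(sqrt(n / elongation)))
  nrr <- ceiling(n / ncc)
  px <- size / ncc
  py <- size / nrr
  g <- expand.grid(i = seq_len(nrr), j = seq_len(ncc))
  keep <- sort(sample.int(nrow(g), n))
  x <- (g$j - 0.5) * px + stats::runif(nrow(g), -jitter, jitter) * px
  y <- (g$i - 0.5) * py + stats::runif(nrow(g), -jitter, jitter) * py
  list(xy = cbind(x = x[keep], y = y[keep]),
       cell = cbind(i = g$i[keep], j = g$j[keep]),
       nrr = nrr, ncc = ncc, px = px, py = py)
}

# nearest-seed assignment with 1-pixel borders between distinct regions
rasterizeVoronoi <- function(seeds, size) {
  xy <- seeds$xy
  n <- nrow(xy)
  xs <- rep(seq_len(size) - 0.5, each = size)   # column-major: y fast
  ys <- rep(seq_len(size) - 0.5, size)
  # candidate seeds from the local lattice neighbourhood of each pixel
  bestD <- rep(Inf, size * size)
  bestL <- rep(0L, size * size)
  pj <- pmin(pmax(ceiling(xs / seeds$px), 1L), seeds$ncc)
  pi_ <- pmin(pmax(ceiling(ys / seeds$py), 1L), seeds$nrr)
  lookup <- matrix(NA_integer_, seeds$nrr, seeds$ncc)
  lookup[seeds$cell] <- seq_len(n)
  for (di in -2:2) for (dj in -2:2) {
    ii <- pi_ + di; jj <- pj + dj
    ok <- ii >= 1L & ii <= seeds$nrr & jj >= 1L & jj <= seeds$ncc
    cand <- rep(NA_integer_, length(xs))
    cand[ok] <- lookup[cbind(ii[ok], jj[ok])]
    has <- !is.na(cand)
    if (!any(has)) next
    d <- (xs[has] - xy[cand[has], 1])^2 + (ys[has] - xy[cand[has], 2])^2
    imp <- d < bestD[has]
    upd <- which(has)[imp]
    bestD[upd] <- d[imp]
    bestL[upd] <- cand[has][imp]
  }
  # any pixel missed by the local search (sparse dropped seeds): exact scan
  miss <- which(bestL == 0L)
  for (p in miss) {
    d <- (xs[p] - xy[, 1])^2 + (ys[p] - xy[, 2])^2
    bestL[p] <- which.min(d)
  }
  mask <- matrix(bestL, size, size)
  # 1-pixel background border wherever the right or lower neighbour differs
  border <- matrix(FALSE, size, size)
  border[, -size] <- border[, -size] | (mask[, -size] != mask[, -1])
  border[-size, ] <- border[-size, ] | (mask[-size, ] != mask[-1, ])
  mask[border] <- 0L
  storage.mode(mask) <- "integer"
  mask
}

#' Assign clustered agonist sensitivities to cells
#'
#' Grows one spatially clustered sensitivity set per agonist ("ACh" and
#' "BK") from randomly seeded interior cells by stochastic neighbour
#' recruitment, then marks a fraction of cells as multisensitive. When
#' \code{bridgePlacement} is on, multisensitive cells are chosen
#' preferentially from cells adjacent to both grown sets (inter-community
#' bridges), falling back to random members of either set; when off they
#' are drawn at random from the union (a null configuration).
#'
#' @param graph a \linkS4class{TissueGraph}.
#' @param config a \linkS4class{SimulationConfig}.
#' @return list with \code{sensitivity} (factor per cell id: ACh, BK,
#'   both, none) and \code{community} (data.frame of cell id, agonist,
#'   community id).
#' @export
assignSensitivities <- function(graph, config) {
  interior <- interiorCells(graph)
  A <- adjacencyMatrix(graph)[interior, interior, drop = FALSE]
  nI <- length(interior)
  targetPer <- max(config@communitySeeds,
                   round(config@sensitiveFrac * nI))
  nOverlap <- round(config@overlapFrac * nI)
  # agonist subpopulations occupy spatially distinct territory: seed each
  # agonist's communities on opposite sides of the field, so the two sets
  # meet along a central interface as in imaged sheets
  geom <- cellGeometry(graph)
  cx <- geom$centroid_x[match(interior, geom$cell_id)]
  leftPool <- which(cx <= stats::quantile(cx, 0.4))
  rightPool <- which(cx >= stats::quantile(cx, 0.6))
  withSeed(deriveSeed(config@rngSeed, 21), {
    setA <- growCommunities(A, config@communitySeeds, targetPer,
                            config@growthProb, exclude = integer(),
                            seedPool = leftPool)
    setB <- growCommunities(A, config@communitySeeds, targetPer,
                            config@growthProb,
                            exclude = unlist(setA),
                            seedPool = rightPool)
    memA <- unlist(setA); memB <- unlist(setB)
    if (nOverlap > length(union(memA, memB)))
      stop("overlapFrac of ", config@overlapFrac,
           " asks for ", nOverlap, " multisensitive cells but only ",
           length(union(memA, memB)), " sensitive cells were grown")
    multi <- integer(0)
    if (nOverlap > 0) {
      pool <- union(memA, memB)
      if (config@bridgePlacement) {
        # bridge positions: sensitive cells nearest (graph distance) to
        # the other agonist's community, and among those the ones with
        # the highest structural betweenness -- multisensitive cells then
        # occupy the inter-community communication bottlenecks
        gI <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
        btw <- igraph::betweenness(gI, directed = FALSE)
        D <- igraph::distances(gI)
        dOther <- vapply(pool, function(v) {
          if (v %in% memA) min(D[v, memB]) else min(D[v, memA])
        }, numeric(1))
        cand <- pool[order(dOther)]
        cand <- utils::head(cand, max(nOverlap, 4 * nOverlap))
        cand <- cand[order(btw[cand], decreasing = TRUE)]
        multi <- utils::head(cand, nOverlap)
      }
      if (length(multi) < nOverlap) {
        extra <- setdiff(pool, multi)
        multi <- c(multi, sample(extra, nOverlap - length(multi)))
      }
    }
    sens <- rep("none", nI)
    sens[memA] <- "ACh"
    sens[memB] <- "BK"
    sens[multi] <- "both"
    names(sens) <- interior
    comm <- rbind(
      communityFrame(setA, "ACh", interior),
      communityFrame(setB, "BK", interior)
    )
    all <- stats::setNames(rep("none", length(cellIds(graph))),
                           cellIds(graph))
    all[names(sens)] <- sens
    list(sensitivity = factor(all, levels = c("ACh", "BK", "both", "none")),
         community = comm)
  })
}

# grow communitySeeds clusters to a combined target size by neighbour
# recruitment with probability growthProb per frontier contact
growCommunities <- function(A, nSeeds, target, growthProb, exclude,
                            seedPool = NULL) {
  nI <- nrow(A)
  avail <- setdiff(seq_len(nI), exclude)
  pool <- if (is.null(seedPool)) avail else intersect(seedPool, avail)
  if (length(pool) < nSeeds) pool <- avail
  seeds <- sample(pool, nSeeds)
  member <- rep(0L, nI)
  member[seeds] <- seq_len(nSeeds)
  size <- nSeeds
  stall <- 0L
  while (size < target && stall < 200L) {
    grown <- FALSE
    for (cid in sample(nSeeds)) {
      if (size >= target) break
      cur <- which(member == cid)
      nbr <- which(rowSums(A[, cur, drop = FALSE]) > 0)
      nbr <- nbr[member[nbr] == 0L & !(nbr %in% exclude)]
      if (length(nbr) == 0L) next
      take <- nbr[stats::runif(length(nbr)) < growthProb]
      if (length(take) == 0L) next
      take <- utils::head(sample(take), target - size)
      member[take] <- cid
      size <- size + length(take)
      grown <- TRUE
    }
    stall <- if (grown) 0L else stall + 1L
  }
  lapply(seq_len(nSeeds), function(cid) which(member == cid))
}

bridgeScore <- function(A, nodes, memA, memB) {
  if (length(nodes) == 0) return(numeric(0))
  pmin(rowSums(A[nodes, memA, drop = FALSE]),
       rowSums(A[nodes, memB, drop = FALSE]))
}

communityFrame <- function(sets, agonist, interior) {
  do.call(rbind, lapply(seq_along(sets), function(i) {
    if (length(sets[[i]]) == 0) return(NULL)
    data.frame(cell_id = interior[sets[[i]]], agonist = agonist,
               community = i)
  }))
}

#' Simulate neighbour-coupled stochastic Ca2+ traces
#'
#' Draws per-cell event onsets from a discrete-time hazard
#' \eqn{\lambda_i(t)\Delta t} with
#' \eqn{\lambda_i(t) = base + s_i r(C)(1 + \beta k_i(t))}, where \eqn{s_i}
#' indicates sensitivity to the applied agonist, \eqn{r(C)} the
#' concentration drive (active after the stimulus onset) and \eqn{k_i(t)}
#' the number of neighbours with an onset within the coupling window. Each
#' onset is rendered as an exponentially modified Gaussian transient added
#' to a baseline of 1 plus white Gaussian noise.
#'
#' @param sensitivity factor per cell id as returned by
#'   \code{\link{assignSensitivities}}.
#' @param graph a \linkS4class{TissueGraph}.
#' @param config a \linkS4class{SimulationConfig}.
#' @param agonist which agonist is applied ("ACh" or "BK").
#' @param concentration molar agonist concentration.
#' @param render if FALSE, skip trace rendering and return onsets only
#'   (fast path for event-level analyses).
#' @return list with \code{traces} (a \linkS4class{TraceSet}, or NULL when
#'   \code{render = FALSE}) and \code{events} (ground-truth event table:
#'   cell_id, onset, peak_time, amplitude, sigma, tau, fdhm).
#' @export
simulateTraces <- function(sensitivity, graph, config,
                           agonist = "ACh", concentration = 1e-6,
                           render = TRUE) {
  ids <- cellIds(graph)
  A <- adjacencyMatrix(graph)
  n <- length(ids)
  dt <- 1 / config@frameRate
  nF <- round(config@duration * config@frameRate)
  onsetFrame <- round(config@stimulusOnset * config@frameRate)
  s <- as.integer(sensitivity[ids] == agonist | sensitivity[ids] == "both")
  logC <- log10(concentration)
  dp <- config@driveParams
  if (config@driveMode == "venous") {
    rate <- fourPL(logC, dp$rateBottom, dp$rateTop, dp$rateLogEC50,
                   dp$rateHill)
    ampMean <- config@eventShape$ampMean
  } else {
    rate <- bellCurve(logC, dp$bellBase, dp$bellHeight, dp$bellCenter,
                      dp$bellWidth)
    ampMean <- fourPL(logC, dp$ampBottom, dp$ampTop, dp$ampLogEC50,
                      dp$ampHill)
  }
  winFrames <- round(config@couplingWindow * config@frameRate)
  maxHaz <- config@baseRate + rate * (1 + config@couplingBeta * max(rowSums(A)))
  if (maxHaz * dt > 0.5)
    stop("time step too coarse for the configured hazard (max lambda*dt = ",
         signif(maxHaz * dt, 3), ")")
  nbrList <- lapply(seq_len(n), function(i) which(A[i, ] > 0))
  withSeed(deriveSeed(config@rngSeed, 31) +
             round(abs(logC) * 1000) %% 100000, {
    k <- rep(0, n)
    expiry <- vector("list", nF + winFrames + 1L)
    onsets <- vector("list", n)
    refFrames <- round(config@refractory * config@frameRate)
    quietUntil <- rep(0L, n)
    for (f in seq_len(nF)) {
      drive <- if (f >= onsetFrame) rate else 0
      lambda <- config@baseRate + s * drive * (1 + config@couplingBeta * k)
      lambda[quietUntil >= f] <- 0
      fired <- which(stats::runif(n) < lambda * dt)
      if (length(fired)) {
        quietUntil[fired] <- f + refFrames
        for (i in fired) onsets[[i]] <- c(onsets[[i]], (f - 1) * dt)
        bump <- unlist(nbrList[fired])
        if (length(bump)) {
          tb <- tabulate(bump, n)
          k <- k + tb
          expiry[[f + winFrames]] <- c(expiry[[f + winFrames]], bump)
        }
      }
      ex <- expiry[[f]]
      if (length(ex)) k <- k - tabulate(ex, n)
    }
    nev <- vapply(onsets, length, integer(1))
    total <- sum(nev)
    es <- config@eventShape
    if (total > 0) {
      sigma <- pmax(0.05, stats::rnorm(total, es$sigmaMean, es$sigmaSd))
      tau <- pmax(0.05, stats::rnorm(total, es$tauMean, es$tauSd))
      # amplitude noise is multiplicative (ampSd is the CV at mean 1),
      # floored at ampFloor F/F0
      amp <- pmax(es$ampFloor,
                  ampMean * stats::rnorm(total, 1, es$ampSd))
      events <- data.frame(
        cell_id = rep(ids, nev),
        onset = unlist(onsets),
        amplitude = amp, sigma = sigma, tau = tau
      )
      pk <- mapply(function(mu, sg, tu) {
        p <- emgPeakInfo(mu, sg, tu)
        c(p$peakTime, p$peakValue)
      }, events$onset + 2 * events$sigma, events$sigma, events$tau)
      events$peak_time <- pk[1, ]
      events$peak_scale <- pk[2, ]
      events$fdhm <- emgFdhm(events$onset + 2 * events$sigma,
                             events$sigma, events$tau, events$peak_scale)
    } else {
      events <- data.frame(cell_id = character(), onset = numeric(),
                           amplitude = numeric(), sigma = numeric(),
                           tau = numeric(), peak_time = numeric(),
                           peak_scale = numeric(), fdhm = numeric())
    }
    traces <- NULL
    if (render) {
      tg <- (seq_len(nF) - 1) * dt
      vals <- matrix(1, nF, n, dimnames = list(NULL, ids))
      if (config@noiseSd > 0)
        vals <- vals + matrix(stats::rnorm(nF * n, 0, config@noiseSd), nF, n)
      if (total > 0) {
        ci <- match(events$cell_id, ids)
        for (e in seq_len(total)) {
          mu <- events$onset[e] + 2 * events$sigma[e]
          lo <- max(1L, 1L + floor((mu - 5 * events$sigma[e]) / dt))
          hi <- min(nF, 1L + ceiling((mu + 6 * events$tau[e] +
                                        5 * events$sigma[e]) / dt))
          if (lo > hi) next
          shape <- emgShape(tg[lo:hi], mu, events$sigma[e], events$tau[e]) /
            events$peak_scale[e]
          vals[lo:hi, ci[e]] <- vals[lo:hi, ci[e]] +
            events$amplitude[e] * shape
        }
      }
      traces <- TraceSet(vals, config@frameRate, config@stimulusOnset)
    }
    events$peak_scale <- NULL
    list(traces = traces, events = events)
  })
}

# FDHM of the scaled EMG transient (width at half of peak), numeric
emgFdhm <- function(mu, sigma, tau, peakScale) {
  mapply(function(m, sg, tu, pkv) {
    dtg <- min(sg, tu) / 20
    tg <- seq(m - 5 * sg, m + 6 * tu + 5 * sg, by = dtg)
    y <- emgShape(tg, m, sg, tu) / pkv
    above <- y >= 0.5
    if (!any(above)) return(NA_real_)
    dtg * sum(above)
  }, mu, sigma, tau, peakScale)
}

#' Simulate a complete synthetic tissue dataset
#'
#' Convenience wrapper: tessellation, graph construction, sensitivity
#' assignment and trace simulation in one call.
#'
#' @inheritParams simulateTraces
#' @param config a \linkS4class{SimulationConfig}.
#' @return list with \code{mask}, \code{graph}, \code{sensitivity},
#'   \code{community}, \code{traces}, \code{events}, \code{config}.
#' @export
simulateTissue <- function(config, agonist = "ACh", concentration = 1e-6,
                           render = TRUE) {
  tess <- generateTessellation(config)
  graph <- buildTissueGraph(tess$mask)
  sens <- assignSensitivities(graph, config)
  sim <- simulateTraces(sens$sensitivity, graph, config,
                        agonist = agonist, concentration = concentration,
                        render = render)
  list(mask = tess$mask, graph = graph, sensitivity = sens$sensitivity,
       community = sens$community, traces = sim$traces,
       events = sim$events, config = config)
}
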