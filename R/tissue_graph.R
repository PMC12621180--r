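#' Assign background pixels to the nearest labelled region
#'
#' Generalized Voronoi expansion of an integer label mask: every background
#' (0) pixel is assigned the label of its nearest labelled pixel (Euclidean
#' distance in pixel units); ties go to the lowest label id. This is the
#' deterministic, parameter-free formalization of expanding cell boundaries
#' until they touch.
#'
#' @param mask integer matrix; 0 = background, k > 0 = cell k.
#' @return integer matrix of the same shape with no background left
#'   (unless the mask has no labels at all).
#' @export
expandLabels <- function(mask) {
  mask <- as.matrix(mask)
  storage.mode(mask) <- "integer"
  nr <- nrow(mask); nc <- ncol(mask)
  unresolved <- which(mask == 0L)
  if (length(unresolved) == 0L || all(mask == 0L)) return(mask)
  out <- mask
  ri <- ((unresolved - 1L) %% nr) + 1L
  ci <- ((unresolved - 1L) %/% nr) + 1L
  bestD <- rep(Inf, length(unresolved))
  bestL <- rep(0L, length(unresolved))
  maxR <- max(nr, nc)
  # offsets are visited in order of increasing squared distance, so the
  # first hit for a pixel is its nearest labelled pixel; equal-distance
  # offsets are processed as one group with lowest-label tie-break.
  r <- 1L
  repeat {
    off <- expand.grid(dy = -r:r, dx = -r:r)
    off <- off[pmax(abs(off$dy), abs(off$dx)) == r, ]
    off$d2 <- off$dy^2 + off$dx^2
    for (d2 in sort(unique(off$d2))) {
      # pixels whose current best is at >= this distance can still improve
      # (strictly closer hit, or an equal-distance hit with a lower label)
      grp <- off[off$d2 == d2, ]
      cand <- which(bestD >= d2)
      if (length(cand) == 0L) next
      for (g in seq_len(nrow(grp))) {
        yy <- ri[cand] + grp$dy[g]
        xx <- ci[cand] + grp$dx[g]
        ok <- yy >= 1L & yy <= nr & xx >= 1L & xx <= nc
        if (!any(ok)) next
        lab <- rep(0L, length(cand))
        lab[ok] <- mask[cbind(yy[ok], xx[ok])]
        hit <- lab > 0L
        if (!any(hit)) next
        idx <- cand[hit]
        better <- bestD[idx] > d2 |
          (bestD[idx] == d2 & lab[hit] < bestL[idx])
        idx <- idx[better]
        bestD[idx] <- d2
        bestL[idx] <- lab[hit][better]
      }
    }
    # a pixel resolved at distance d can only be beaten by offsets with
    # d' < d; all offsets with Euclidean distance <= r have been seen once
    # Chebyshev radius ceiling(d) is reached
    done <- bestL > 0L & sqrt(bestD) <= r
    if (all(done) || r > maxR) break
    r <- r + 1L
  }
  out[unresolved] <- bestL
  out
}

# pixel-pair contact counts between distinct labels in a fully labelled
# image, 4-connectivity; returns data.frame(a, b, count) with a < b
contactCounts <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[, -nc]), as.vector(lab[, -1])),
    cbind(as.vector(lab[-nr, ]), as.vector(lab[-1, ]))
  )
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs) == 0L)
    return(data.frame(a = integer(), b = integer(), count = integer()))
  a <- pmin(pairs[, 1], pairs[, 2])
  b <- pmax(pairs[, 1], pairs[, 2])
  key <- paste(a, b)
  tab <- table(key)
  ab <- do.call(rbind, strsplit(names(tab), " "))
  data.frame(a = as.integer(ab[, 1]), b = as.integer(ab[, 2]),
             count = as.integer(tab))
}

# per-label geometry from the original mask pixels
maskGeometry <- function(mask) {
  labs <- sort(unique(as.vector(mask)))
  labs <- labs[labs > 0]
  nr <- nrow(mask); nc <- ncol(mask)
  res <- lapply(labs, function(k) {
    idx <- which(mask == k)
    y <- ((idx - 1L) %% nr) + 1L
    x <- ((idx - 1L) %/% nr) + 1L
    # aspect ratio from principal axes of the pixel cloud
    if (length(idx) > 1L) {
      ev <- eigen(stats::cov(cbind(x, y)), symmetric = TRUE,
                  only.values = TRUE)$values
      ev <- pmax(ev, 1 / 12)  # single-row regions: pixel quantization floor
      ratio <- sqrt(ev[1] / ev[2])
    } else ratio <- 1
    data.frame(cell_id = as.character(k),
               centroid_x = mean(x) - 1, centroid_y = mean(y) - 1,
               area = length(idx), aspect_ratio = ratio,
               frame_touching = any(y == 1L | y == nr | x == 1L | x == nc))
  })
  do.call(rbind, res)
}

#' Build the cell-adjacency network from a label mask
#'
#' Background pixels are assigned to the nearest label
#' (\code{\link{expandLabels}}); two cells are neighbours when their
#' expanded regions share at least \code{minContacts} four-connected pixel
#' contacts (the default of 2 suppresses corner-only artifacts).
#'
#' @param mask integer label mask (0 = background).
#' @param minContacts minimum number of touching pixel pairs for an edge.
#' @param alpha concavity parameter (pixels) passed to
#'   \code{\link{markBoundaryCells}}; \code{NULL} for its default.
#' @return A \linkS4class{TissueGraph}.
#' @export
buildTissueGraph <- function(mask, minContacts = 2, alpha = NULL) {
  mask <- as.matrix(mask)
  storage.mode(mask) <- "integer"
  labs <- sort(unique(as.vector(mask)))
  labs <- labs[labs > 0]
  if (length(labs) < 2)
    stop("mask must contain at least 2 labels")
  ids <- as.character(labs)
  expanded <- expandLabels(mask)
  cc <- contactCounts(expanded)
  cc <- cc[cc$count >= minContacts, , drop = FALSE]
  A <- matrix(0, length(labs), length(labs), dimnames = list(ids, ids))
  if (nrow(cc) > 0) {
    ai <- match(as.character(cc$a), ids)
    bi <- match(as.character(cc$b), ids)
    A[cbind(ai, bi)] <- 1
    A[cbind(bi, ai)] <- 1
  }
  geom <- maskGeometry(mask)
  boundary <- markBoundaryCells(mask, alpha = alpha)
  boundary <- boundary[ids]
  new("TissueGraph", adjacency = A, boundary = boundary, geometry = geom)
}

#' Flag boundary cells via a concave hull of the cell pixels
#'
#' The field-of-view outline is computed as a concave hull of the labelled
#' pixels, operationalized on the raster as a morphological closing of the
#' cell-pixel foreground with a disc of radius \code{alpha/2} followed by
#' hole filling. A cell is a boundary cell when any of its pixels lies on
#' the outline of that closed region or touches the image frame. If the
#' closing fails to produce a single region (alpha too small), the convex
#' hull of the labelled pixels is used instead, with a warning.
#'
#' @param mask integer label mask.
#' @param alpha concavity parameter in pixels; default is twice the median
#'   equivalent cell diameter.
#' @return named logical vector over cell ids, TRUE = boundary.
#' @export
markBoundaryCells <- function(mask, alpha = NULL) {
  mask <- as.matrix(mask)
  labs <- sort(unique(as.vector(mask)))
  labs <- labs[labs > 0]
  ids <- as.character(labs)
  nr <- nrow(mask); nc <- ncol(mask)
  areas <- tabulate(match(as.vector(mask), labs))
  if (is.null(alpha))
    alpha <- 2 * stats::median(2 * sqrt(areas / pi))
  fg <- mask > 0
  radius <- max(1, round(alpha / 2))
  side <- 2L * as.integer(radius) + 1L
  brush <- EBImage::makeBrush(side, shape = "disc")
  closed <- EBImage::fillHull(EBImage::closing(EBImage::Image(fg * 1), brush))
  closedM <- as.matrix(EBImage::imageData(closed)) > 0
  # closing must bridge inter-cell gaps into one region; otherwise fall
  # back to the convex hull of the labelled pixels
  lab <- EBImage::bwlabel(EBImage::Image(closedM * 1))
  nComp <- max(as.matrix(EBImage::imageData(lab)))
  if (nComp != 1L) {
    warning("concave hull degenerate (", nComp,
            " components); falling back to convex hull")
    idx <- which(fg)
    y <- ((idx - 1L) %% nr) + 1L
    x <- ((idx - 1L) %/% nr) + 1L
    h <- grDevices::chull(x, y)
    closedM <- pointsInPolygon(nr, nc, x[h], y[h])
  }
  # outline = closed-region pixels with a 4-neighbour outside the region
  pad <- rbind(FALSE, cbind(FALSE, closedM, FALSE), FALSE)
  inner <- pad[2:(nr + 1), 2:(nc + 1)] &
    pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
    pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)]
  outline <- closedM & !inner
  flagged <- vapply(labs, function(k) {
    idx <- which(mask == k)
    y <- ((idx - 1L) %% nr) + 1L
    x <- ((idx - 1L) %/% nr) + 1L
    any(outline[idx]) || any(y == 1L | y == nr | x == 1L | x == nc)
  }, logical(1))
  names(flagged) <- ids
  flagged
}

# rasterize the interior of a polygon (used by the convex-hull fallback)
pointsInPolygon <- function(nr, nc, px, py) {
  out <- matrix(FALSE, nr, nc)
  xs <- rep(seq_len(nc), each = nr)
  ys <- rep(seq_len(nr), nc)
  n <- length(px)
  inside <- rep(FALSE, nr * nc)
  j <- n
  for (i in seq_len(n)) {
    cond <- ((py[i] > ys) != (py[j] > ys)) &
      (xs < (px[j] - px[i]) * (ys - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, cond & !is.na(cond))
    j <- i
  }
  out[] <- inside
  out
}

#' Summary statistics of interior cells
#'
#' Mean and standard error of the neighbour count, area and length/width
#' ratio over interior (non-boundary) cells. Neighbour counts are degrees
#' in the full structural network (connections to boundary cells count).
#'
#' @param graph a \linkS4class{TissueGraph}.
#' @return data.frame with one row per statistic: mean, sem, n.
#' @export
graphStats <- function(graph) {
  interior <- interiorCells(graph)
  if (length(interior) == 0)
    stop("no interior cells")
  A <- adjacencyMatrix(graph)
  deg <- rowSums(A)[interior]
  geom <- cellGeometry(graph)
  gi <- geom[match(interior, geom$cell_id), ]
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  data.frame(
    statistic = c("neighbors", "area", "aspect_ratio"),
    mean = c(mean(deg), mean(gi$area), mean(gi$aspect_ratio)),
    sem = c(sem(deg), sem(gi$area), sem(gi$aspect_ratio)),
    n = length(interior)
  )
}
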