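# fixtures and independent oracles shared across test files

# rectangular block mask: nr x nc blocks of blockw px separated by 1-px
# background gaps; labels 1..nr*nc in row-major block order
makeBlockMask <- function(nr, nc, blockw = 5) {
  side <- function(n) n * blockw + (n - 1)
  m <- matrix(0L, side(nr), side(nc))
  lab <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    lab <- lab + 1L
    r0 <- (i - 1) * (blockw + 1)
    c0 <- (j - 1) * (blockw + 1)
    m[r0 + seq_len(blockw), c0 + seq_len(blockw)] <- lab
  }
  m
}

# oracle: exact nearest-label assignment by full scan (ties -> lowest label)
bruteForceExpand <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- which(mask > 0)
  ly <- ((lab - 1) %% nr) + 1
  lx <- ((lab - 1) %/% nr) + 1
  lv <- mask[lab]
  out <- mask
  for (p in which(mask == 0)) {
    py <- ((p - 1) %% nr) + 1
    px <- ((p - 1) %/% nr) + 1
    d <- (py - ly)^2 + (px - lx)^2
    dmin <- min(d)
    out[p] <- min(lv[d == dmin])
  }
  out
}

# oracle: edge set by brute-force pairwise contact enumeration over the
# expanded mask (4-connectivity, threshold on touching pixel pairs)
bruteForceEdges <- function(mask, minContacts = 2) {
  lab <- bruteForceExpand(mask)
  nr <- nrow(lab); nc <- ncol(lab)
  counts <- list()
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    for (d in list(c(0, 1), c(1, 0))) {
      i2 <- i + d[1]; j2 <- j + d[2]
      if (i2 > nr || j2 > nc) next
      a <- lab[i, j]; b <- lab[i2, j2]
      if (a == b) next
      key <- paste(min(a, b), max(a, b))
      counts[[key]] <- (counts[[key]] %||% 0) + 1
    }
  }
  keys <- names(counts)[unlist(counts) >= minContacts]
  if (length(keys) == 0)
    return(matrix(numeric(0), ncol = 2))
  t(vapply(strsplit(keys, " "),
           function(v) sort(as.numeric(v)), numeric(2)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# canonical sorted edge matrix from a TissueGraph for comparison
edgeSet <- function(graph) {
  A <- adjacencyMatrix(graph)
  e <- which(A == 1, arr.ind = TRUE)
  e <- e[e[, 1] < e[, 2], , drop = FALSE]
  ids <- as.numeric(rownames(A))
  m <- cbind(ids[e[, 1]], ids[e[, 2]])
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

sortEdges <- function(m) {
  if (nrow(m) == 0) return(m)
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# oracle: betweenness by exhaustive shortest-path enumeration (DFS over
# the BFS predecessor DAG), independent of igraph
bruteBetweenness <- function(A) {
  n <- nrow(A)
  bc <- numeric(n)
  allPaths <- function(s, t) {
    # BFS distances from s
    dist <- rep(Inf, n); dist[s] <- 0
    q <- s
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      for (w in which(A[v, ] > 0)) if (dist[w] > dist[v] + 1) {
        dist[w] <- dist[v] + 1; q <- c(q, w)
      }
    }
    if (!is.finite(dist[t])) return(list())
    paths <- list()
    dfs <- function(v, acc) {
      if (v == s) { paths[[length(paths) + 1]] <<- rev(acc); return() }
      for (u in which(A[v, ] > 0)) if (dist[u] == dist[v] - 1)
        dfs(u, c(acc, u))
    }
    dfs(t, t)
    paths
  }
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    ps <- allPaths(s, t)
    if (length(ps) == 0) next
    for (p in ps) {
      inner <- setdiff(p, c(s, t))
      bc[inner] <- bc[inner] + 1 / length(ps)
    }
  }
  bc
}

# random symmetric adjacency matrix with no self loops
randomAdjacency <- function(n, p = 0.4) {
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- as.numeric(stats::runif(n * (n - 1) / 2) < p)
  A + t(A)
}

# wrap an adjacency matrix as a TissueGraph with no boundary cells
graphFromAdjacency <- function(A, boundary = NULL) {
  ids <- as.character(seq_len(nrow(A)))
  dimnames(A) <- list(ids, ids)
  if (is.null(boundary))
    boundary <- stats::setNames(rep(FALSE, nrow(A)), ids)
  geom <- data.frame(cell_id = ids, centroid_x = 0, centroid_y = 0,
                     area = 1, aspect_ratio = 1, frame_touching = FALSE)
  new("TissueGraph", adjacency = A, boundary = boundary, geometry = geom)
}

# greedy ground-truth matching of detected to true events (1-s tolerance)
matchEvents <- function(truth, detected, tol = 1) {
  matched <- logical(nrow(truth))
  used <- logical(nrow(detected))
  for (i in seq_len(nrow(truth))) {
    cand <- which(detected$cell_id == truth$cell_id[i] & !used &
                    abs(detected$peak_time - truth$peak_time[i]) <= tol)
    if (length(cand)) { matched[i] <- TRUE; used[cand[1]] <- TRUE }
  }
  list(recall = mean(matched), precision = mean(used))
}

# render a single EMG transient on a baseline of 1 (written out directly:
# Gaussian convolved with an exponential decay, peak-normalized)
renderEmg <- function(nFrames, frameRate, mu, sigma, tau, amplitude,
                      noiseSd = 0) {
  tg <- (seq_len(nFrames) - 1) / frameRate
  z <- (tg - mu) / sigma - sigma / tau
  shape <- exp(sigma^2 / (2 * tau^2) - (tg - mu) / tau +
                 stats::pnorm(z, log.p = TRUE))
  y <- 1 + amplitude * shape / max(shape)
  if (noiseSd > 0) y <- y + stats::rnorm(nFrames, 0, noiseSd)
  y
}
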