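#' Betweenness centrality of interior cells
#'
#' Unnormalized shortest-path betweenness on the interior-node induced
#' subgraph (unweighted, undirected): for each node, the sum over
#' unordered pairs of other nodes of the fraction of shortest paths
#' passing through it. Disconnected graphs are handled per component
#' (unreachable pairs contribute nothing).
#'
#' @param graph a \linkS4class{TissueGraph}.
#' @return named numeric vector over interior cell ids.
#' @export
nodeBetweenness <- function(graph) {
  g <- asIgraph(graph)
  igraph::betweenness(g, directed = FALSE, normalized = FALSE)
}

#' Spectral summary of the interior adjacency matrix
#'
#' Full symmetric eigendecomposition of the interior adjacency matrix A,
#' eigenvalues sorted descending. The leading eigenvector (eigenvector
#' centrality) is sign-fixed nonnegative. Eigengaps g_i = lambda_i -
#' lambda_{i+1} are reported and the dominant local community scale i* is
#' the argmax of g_i over 1 < i <= min(n-1, 20), smallest i on ties.
#' Since A is symmetric the left and right eigenvectors coincide.
#'
#' @param graph a \linkS4class{TissueGraph}.
#' @return list: values, vectors (columns, unit L2 norm), gaps, iStar,
#'   connected flag.
#' @export
spectralSummary <- function(graph) {
  interior <- interiorCells(graph)
  stopifnot(length(interior) >= 2)
  A <- adjacencyMatrix(graph)[interior, interior, drop = FALSE]
  e <- eigen(A, symmetric = TRUE)
  v <- e$vectors
  rownames(v) <- interior
  # Perron vector of a connected graph is sign-definite; orient positive
  if (sum(v[, 1]) < 0) v[, 1] <- -v[, 1]
  n <- length(interior)
  gaps <- e$values[-n] - e$values[-1]
  iMax <- min(n - 1L, 20L)
  cand <- if (iMax >= 2L) 2:iMax else integer(0)
  iStar <- if (length(cand)) cand[which.max(gaps[cand])] else 1L
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  connected <- igraph::is_connected(g)
  if (!connected)
    message("interior graph is disconnected; spectrum computed on full A")
  list(values = e$values, vectors = v, gaps = gaps, iStar = iStar,
       connected = connected)
}

#' Local influence scores from the leading eigenvectors
#'
#' Each node's score is the L2 norm of its components across the first
#' i* eigenvectors (i* from the dominant eigengap). The secondary
#' community-of-influence assignment is the argmax over j <= i* of
#' |v_j(node)|.
#'
#' @param spectral result of \code{\link{spectralSummary}}.
#' @return data.frame: cell_id, local_influence, influence_community.
#' @export
localInfluence <- function(spectral) {
  V <- spectral$vectors[, seq_len(spectral$iStar), drop = FALSE]
  data.frame(cell_id = rownames(V),
             local_influence = sqrt(rowSums(V^2)),
             influence_community = apply(abs(V), 1, which.max))
}

#' Per-node centrality table
#'
#' Betweenness, global eigenvector centrality (leading-eigenvector
#' component) and eigengap-based local influence for every interior cell.
#'
#' @param graph a \linkS4class{TissueGraph}.
#' @return data.frame: cell_id, betweenness, global_eigen,
#'   local_influence, influence_community.
#' @export
centralityTable <- function(graph) {
  bt <- nodeBetweenness(graph)
  sp <- spectralSummary(graph)
  li <- localInfluence(sp)
  data.frame(cell_id = names(bt),
             betweenness = unname(bt),
             global_eigen = unname(sp$vectors[names(bt), 1]),
             local_influence = li$local_influence[match(names(bt),
                                                        li$cell_id)],
             influence_community = li$influence_community[match(names(bt),
                                                                li$cell_id)])
}

#' Mean centralities of agonist-responder groups
#'
#' Splits two agonists' responder sets into ACh-only, BK-only and
#' multisensitive (intersection) groups and reports the mean of each
#' centrality over each group. Empty groups are flagged and skipped.
#'
#' @param table centrality table from \code{\link{centralityTable}}.
#' @param respondersA,respondersB responder cell ids for the two agonists.
#' @param labels group labels for the two set differences.
#' @return data.frame with one row per group x centrality.
#' @export
groupCentrality <- function(table, respondersA, respondersB,
                            labels = c("ACh-only", "BK-only")) {
  groups <- list(setdiff(respondersA, respondersB),
                 setdiff(respondersB, respondersA),
                 intersect(respondersA, respondersB))
  names(groups) <- c(labels, "multisensitive")
  out <- do.call(rbind, lapply(names(groups), function(gn) {
    g <- groups[[gn]]
    if (length(g) == 0)
      return(data.frame(group = gn, n = 0, betweenness = NA_real_,
                        global_eigen = NA_real_, local_influence = NA_real_,
                        empty = TRUE))
    rows <- table[table$cell_id %in% g, , drop = FALSE]
    data.frame(group = gn, n = nrow(rows),
               betweenness = mean(rows$betweenness),
               global_eigen = mean(rows$global_eigen),
               local_influence = mean(rows$local_influence),
               empty = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Permutation null for group centrality means
#'
#' For each group, resamples node sets of the same size uniformly from the
#' interior cells, recomputes the group-mean centrality per draw, and
#' reports the observed mean with the null mean/SD and its empirical
#' percentile.
#'
#' @param graph a \linkS4class{TissueGraph}.
#' @param groups named list of observed cell-id groups.
#' @param nPerm number of permutations (default 100).
#' @param seed integer seed.
#' @param table optional precomputed \code{\link{centralityTable}}.
#' @return nested list: one element per group, each a named list of
#'   permutation-null records per centrality.
#' @export
centralityPermutationNull <- function(graph, groups, nPerm = 100, seed = 1,
                                      table = NULL) {
  if (is.null(table)) table <- centralityTable(graph)
  interior <- table$cell_id
  cents <- c("betweenness", "global_eigen", "local_influence")
  withSeed(seed, {
    res <- lapply(names(groups), function(gn) {
      g <- as.character(groups[[gn]])
      stopifnot(length(g) <= length(interior))
      if (length(g) == 0) return(NULL)
      obs <- colMeans(table[table$cell_id %in% g, cents, drop = FALSE])
      null <- vapply(seq_len(nPerm), function(i) {
        draw <- sample(interior, length(g))
        colMeans(table[table$cell_id %in% draw, cents, drop = FALSE])
      }, numeric(length(cents)))
      null <- matrix(null, nrow = length(cents),
                     dimnames = list(cents, NULL))
      recs <- lapply(cents, function(cn)
        nullRecord(cn, obs[[cn]], null[cn, ]))
      names(recs) <- cents
      recs
    })
    names(res) <- names(groups)
    res
  })
}
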