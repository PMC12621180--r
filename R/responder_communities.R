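#' Select the top fraction of interior cells by response frequency
#'
#' Ranks interior cells by response frequency (descending), breaking ties
#' by mean amplitude (descending) then cell id (ascending), and returns
#' exactly \code{ceiling(fraction * n)} cells.
#'
#' @param summaries per-cell summaries (\code{\link{summarizeCells}})
#'   restricted to interior cells.
#' @param fraction fraction of cells to keep (default 0.20).
#' @return character vector of selected cell ids.
#' @export
selectTopResponders <- function(summaries, fraction = 0.2) {
  stopifnot(fraction > 0, fraction <= 1)
  n <- nrow(summaries)
  k <- ceiling(fraction * n)
  amp <- summaries$mean_amplitude
  amp[is.na(amp)] <- -Inf
  ord <- order(-summaries$frequency, -amp,
               as.character(summaries$cell_id))
  as.character(summaries$cell_id)[ord[seq_len(k)]]
}

#' Partition responders into spatial communities and isolated cells
#'
#' A community is a connected component (size >= 2) of the subgraph
#' induced by the responder set on the tissue graph; responders with no
#' responding neighbour are isolated.
#'
#' @param graph a \linkS4class{TissueGraph}.
#' @param responders character vector of responder cell ids (interior).
#' @return list with \code{communities} (list of cell-id vectors) and
#'   \code{isolated} (cell ids).
#' @export
findCommunities <- function(graph, responders) {
  responders <- sort(as.character(responders))
  if (length(responders) == 0)
    return(list(communities = list(), isolated = character()))
  A <- adjacencyMatrix(graph)[responders, responders, drop = FALSE]
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  comp <- igraph::components(g)
  groups <- split(responders, comp$membership)
  sizes <- lengths(groups)
  list(communities = unname(groups[sizes >= 2]),
       isolated = unname(unlist(groups[sizes == 1])) %||% character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Clustering metrics of a responder partition
#'
#' Degree of clustering is the mean, over community members, of their
#' degree in the responder-induced subgraph; the clustering coefficient is
#' the mean local clustering coefficient of community members on that same
#' subgraph (members of degree < 2 contribute 0). Isolated responders are
#' excluded from both averages.
#'
#' @param graph a \linkS4class{TissueGraph}.
#' @param partition result of \code{\link{findCommunities}}.
#' @return list: n_communities, mean_community_size, n_isolated,
#'   degree_of_clustering, clustering_coefficient, has_communities.
#' @export
communityMetrics <- function(graph, partition) {
  members <- unlist(partition$communities)
  active <- c(members, partition$isolated)
  if (length(members) == 0) {
    return(list(n_communities = 0, mean_community_size = 0,
                n_isolated = length(partition$isolated),
                degree_of_clustering = 0, clustering_coefficient = 0,
                has_communities = FALSE))
  }
  A <- adjacencyMatrix(graph)[active, active, drop = FALSE]
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  deg <- igraph::degree(g)[members]
  cc <- igraph::transitivity(g, type = "localundirected",
                             vids = members, isolates = "zero")
  list(n_communities = length(partition$communities),
       mean_community_size = mean(lengths(partition$communities)),
       n_isolated = length(partition$isolated),
       degree_of_clustering = mean(deg),
       clustering_coefficient = mean(cc),
       has_communities = TRUE)
}

#' Permutation null for responder clustering metrics
#'
#' Draws \code{nPerm} random responder sets of the same size as the
#' observed set, uniformly without replacement from the interior cells,
#' recomputes the clustering metrics for each, and reports the observed
#' value against the null distribution (mean, SD, empirical percentile).
#'
#' @param graph a \linkS4class{TissueGraph}.
#' @param responders observed responder cell ids.
#' @param nPerm number of permutations (default 100).
#' @param seed integer seed for the permutation stream.
#' @param metrics which metrics to report.
#' @return named list of permutation-null records (one per metric), each
#'   with observed, null values, nullMean, nullSd and percentile.
#' @export
clusteringPermutationNull <- function(graph, responders, nPerm = 100,
                                      seed = 1,
                                      metrics = c("degree_of_clustering",
                                                  "clustering_coefficient",
                                                  "n_communities",
                                                  "mean_community_size",
                                                  "n_isolated")) {
  interior <- interiorCells(graph)
  nActive <- length(responders)
  stopifnot(nActive <= length(interior))
  obs <- communityMetrics(graph, findCommunities(graph, responders))
  null <- withSeed(seed, {
    vapply(seq_len(nPerm), function(i) {
      draw <- sample(interior, nActive)
      m <- communityMetrics(graph, findCommunities(graph, draw))
      unlist(m[metrics])
    }, numeric(length(metrics)))
  })
  null <- matrix(null, nrow = length(metrics),
                 dimnames = list(metrics, NULL))
  res <- lapply(metrics, function(mt)
    nullRecord(mt, obs[[mt]], null[mt, ]))
  names(res) <- metrics
  res
}
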