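#' Project a gene list onto an interactome
#'
#' Induces the subgraph of the interactome over the query genes and counts
#' genes with at least one induced interaction, isolated genes (including
#' genes absent from the interactome), and induced edges.
#'
#' @param genes Character vector of query gene ids.
#' @param graph Undirected simple \code{igraph} interactome.
#' @return List with \code{subgraph} (induced \code{igraph} over the query
#'   genes present in the interactome), \code{n_connected},
#'   \code{n_isolated}, \code{n_edges}.
#' @export
projectOntoInteractome <- function(genes, graph) {
  genes <- unique(genes)
  present <- intersect(genes, igraph::V(graph)$name)
  sub <- igraph::induced_subgraph(graph, present)
  deg <- igraph::degree(sub)
  n_conn <- sum(deg > 0)
  list(subgraph = sub,
       n_connected = n_conn,
       n_isolated = length(genes) - n_conn,
       n_edges = igraph::ecount(sub))
}

#' Largest connected component
#'
#' @param graph Nonempty \code{igraph} graph.
#' @return Sorted character vector of node names in the maximum-cardinality
#'   connected component; size ties are broken by the lexicographically
#'   smallest member.
#' @export
largestConnectedComponent <- function(graph) {
  if (igraph::vcount(graph) == 0L) stop("empty graph")
  comp <- igraph::components(graph)
  members <- split(igraph::V(graph)$name, comp$membership)
  members <- lapply(members, sort)
  sizes <- lengths(members)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    firsts <- vapply(members[best], `[[`, character(1), 1L)
    best <- best[order(firsts)][1]
  }
  members[[best]]
}

#' Node centralities: degree, harmonic closeness, betweenness
#'
#' Degree, harmonic closeness (sum of reciprocal shortest-path distances,
#' so disconnected graphs are handled without division by infinity), and
#' Brandes shortest-path betweenness, plus per-measure ranks (1 = highest,
#' average ranks on ties).
#'
#' @param graph Undirected simple \code{igraph}.
#' @return \code{data.frame}: node, degree, closeness, betweenness, and
#'   rank columns for each measure.
#' @export
centralityTable <- function(graph) {
  deg <- igraph::degree(graph)
  clo <- igraph::harmonic_centrality(graph, normalized = FALSE)
  btw <- igraph::betweenness(graph, directed = FALSE)
  data.frame(node = igraph::V(graph)$name,
             degree = as.numeric(deg),
             closeness = as.numeric(clo),
             betweenness = as.numeric(btw),
             rank_degree = rank(-deg, ties.method = "average"),
             rank_closeness = rank(-clo, ties.method = "average"),
             rank_betweenness = rank(-btw, ties.method = "average"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Select hub molecules
#'
#' Hubs are the nodes shared by the top-\code{fraction} ranks of all three
#' centrality measures (degree, harmonic closeness, betweenness). The
#' cutoff is \code{ceiling(fraction * n)} per measure; a value tie
#' straddling the cutoff admits every tied node.
#'
#' @param tab Centrality table from \code{\link{centralityTable}}.
#' @param fraction Top fraction per measure, in (0, 1]; 0.10 is the
#'   conventional hub decile.
#' @return Sorted character vector of hub node names.
#' @export
selectHubs <- function(tab, fraction = 0.10) {
  stopifnot(nrow(tab) > 0, fraction > 0, fraction <= 1)
  k <- ceiling(fraction * nrow(tab))
  topSet <- function(v) {
    thr <- sort(v, decreasing = TRUE)[k]
    tab$node[v >= thr]
  }
  hubs <- Reduce(intersect, list(topSet(tab$degree),
                                 topSet(tab$closeness),
                                 topSet(tab$betweenness)))
  sort(hubs)
}

#' DEG interactome analysis
#'
#' Convenience wrapper running projection, LCC extraction, centrality
#' computation and hub selection on the DEG-induced subgraph.
#'
#' @param genes Query gene ids (e.g. upregulated DEGs).
#' @param graph Interactome \code{igraph}.
#' @param hub_fraction Top fraction for hub selection.
#' @param lcc_only Rank hubs within the largest connected component only,
#'   instead of the whole induced network (the default).
#' @return List: \code{projection}, \code{lcc} (node names),
#'   \code{centrality}, \code{hubs}.
#' @export
analyzeDEGNetwork <- function(genes, graph, hub_fraction = 0.10,
                              lcc_only = FALSE) {
  proj <- projectOntoInteractome(genes, graph)
  if (igraph::vcount(proj$subgraph) == 0L)
    return(list(projection = proj, lcc = character(0),
                centrality = NULL, hubs = character(0)))
  lcc <- largestConnectedComponent(proj$subgraph)
  target <- if (lcc_only)
    igraph::induced_subgraph(proj$subgraph, lcc) else proj$subgraph
  cent <- centralityTable(target)
  list(projection = proj, lcc = lcc, centrality = cent,
       hubs = selectHubs(cent, hub_fraction))
}
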