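#' h-layer neighborhood of a node
#'
#' Nodes reachable from \code{g} within \code{h} directed steps
#' (breadth-first over child edges), excluding \code{g} itself. The
#' \code{undirected} direction ignores edge orientation.
#'
#' @param graph Directed \code{igraph} network.
#' @param g Node name (must exist in the network).
#' @param h Layer depth (>= 1).
#' @param direction "downstream" (default) or "undirected".
#' @return Character vector of neighborhood node names.
#' @export
hLayerNeighborhood <- function(graph, g, h,
                               direction = c("downstream", "undirected")) {
  direction <- match.arg(direction)
  if (!g %in% igraph::V(graph)$name) stop("node '", g, "' not in network")
  if (h < 1L) stop("layer depth h must be >= 1")
  nb <- igraph::ego(graph, order = h, nodes = g,
                    mode = if (direction == "downstream") "out" else "all",
                    mindist = 1L)[[1]]
  nb$name
}

#' Candidate subnetwork around a target gene set
#'
#' The union of the target genes present in the network with every node
#' within \code{H} layers of any of them, searched in both edge
#' orientations so upstream regulators enter the candidate pool.
#'
#' @param graph Directed \code{igraph}.
#' @param G Character vector, the target gene set.
#' @param H Maximum layer depth (>= 1).
#' @return Sorted character vector of candidate node names.
#' @export
buildSubnetworkNG <- function(graph, G, H) {
  if (H < 1L) stop("H must be >= 1")
  present <- intersect(G, igraph::V(graph)$name)
  if (length(present) == 0L)
    stop("target set has no members in the network")
  nb <- igraph::ego(graph, order = H, nodes = present, mode = "all",
                    mindist = 0L)
  sort(unique(unlist(lapply(nb, function(v) v$name))))
}

#' Key driver analysis
#'
#' For every candidate node in the subnetwork around the target set
#' \code{G}, tests the enrichment of its h-layer neighborhoods
#' (h = 1..H) for \code{G} by one-sided Fisher's exact test against the
#' background of all other network nodes, with the candidate itself
#' excluded from its own neighborhood, target set and background. The
#' enrichment statistic is \eqn{ES_{h,g} = -\log_{10} p_{h,g}}; the optimal
#' layer h* maximizes it (smallest h on ties), and key drivers are the
#' candidates whose Bonferroni-corrected p at h* falls below \code{alpha}.
#' Drivers without any parent (root nodes) are labeled \code{global}, the
#' rest \code{local}.
#'
#' @param graph Directed \code{igraph} network (acyclicity is checked; a
#'   cyclic input gives a warning, with scopes still taken from in-degree).
#' @param G Character vector, the target gene set.
#' @param H Maximum layer depth (default 3).
#' @param alpha Bonferroni-corrected significance cutoff (default 0.01).
#' @param direction Neighborhood orientation, see
#'   \code{\link{hLayerNeighborhood}}.
#' @return \code{data.frame}, one row per tested candidate, sorted by
#'   corrected p then gene id: gene, h_star, ES, p, p_adj, scope, hln_size,
#'   overlap, key_driver (logical). The number of tests is attached as
#'   attribute \code{"m_tests"}.
#' @export
keyDriverAnalysis <- function(graph, G, H = 3L, alpha = 0.01,
                              direction = c("downstream", "undirected")) {
  direction <- match.arg(direction)
  if (igraph::vcount(graph) == 0L) stop("empty network")
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  if (!igraph::is_dag(graph))
    warning("network is cyclic; global/local scopes taken from in-degree")
  nodes <- igraph::V(graph)$name
  Gp <- intersect(G, nodes)
  if (length(Gp) == 0L) stop("target set has no members in the network")
  NG <- buildSubnetworkNG(graph, Gp, H)
  m <- length(NG)
  N <- length(nodes)
  indeg <- igraph::degree(graph, mode = "in")
  names(indeg) <- nodes

  rows <- lapply(NG, function(g) {
    Gx <- setdiff(Gp, g)
    best <- list(p = Inf, h = NA_integer_, hln = 0L, ov = 0L)
    for (h in seq_len(H)) {
      hln <- hLayerNeighborhood(graph, g, h, direction)
      ov <- length(intersect(hln, Gx))
      p <- stats::phyper(ov - 1, length(Gx), N - 1 - length(Gx),
                         length(hln), lower.tail = FALSE)
      if (p < best$p) best <- list(p = p, h = h, hln = length(hln), ov = ov)
    }
    data.frame(gene = g, h_star = best$h, ES = -log10(best$p), p = best$p,
               p_adj = min(1, best$p * m),
               scope = if (indeg[[g]] == 0L) "global" else "local",
               hln_size = best$hln, overlap = best$ov,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$key_driver <- out$p_adj < alpha
  out <- out[order(out$p_adj, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "m_tests") <- m
  out
}

#' Correlate candidate-driver expression with a pathway score
#'
#' Pearson correlation (with t-based p) of each gene's expression vector
#' against one pathway's per-sample enrichment scores.
#'
#' @param expr Gene-by-sample expression matrix (candidate genes).
#' @param pathway_scores Numeric vector of per-sample scores, aligned to
#'   the expression columns.
#' @return \code{data.frame}: gene, r, p.
#' @export
correlateKDGScores <- function(expr, pathway_scores) {
  stopifnot(is.matrix(expr), ncol(expr) == length(pathway_scores))
  res <- t(apply(expr, 1, function(v) {
    at <- associationTests(x = v, y = as.numeric(pathway_scores))
    c(at$r, at$p)
  }))
  data.frame(gene = rownames(expr), r = res[, 1], p = res[, 2],
             stringsAsFactors = FALSE, row.names = NULL)
}
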