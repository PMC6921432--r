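#' Over-representation analysis by Fisher's exact test
#'
#' One-sided (enrichment) hypergeometric test of the overlap between a
#' query gene list and a target gene set against a finite universe, with an
#' odds ratio (Haldane 0.5 correction when a table cell is zero).
#'
#' @param query Character vector of query genes (subset of universe).
#' @param target Character vector, the gene set tested (subset of universe).
#' @param universe Character vector, the finite gene universe.
#' @return List with \code{overlap}, \code{odds_ratio}, \code{p}
#'   (one-sided, greater).
#' @export
fisherORA <- function(query, target, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty gene universe")
  query <- unique(intersect(query, universe))
  target <- unique(intersect(target, universe))
  a <- length(intersect(query, target))
  b <- length(query) - a
  c_ <- length(target) - a
  d <- length(universe) - a - b - c_
  p <- stats::phyper(a - 1, length(target),
                     length(universe) - length(target),
                     length(query), lower.tail = FALSE)
  cells <- c(a, b, c_, d)
  if (any(cells == 0)) cells <- cells + 0.5
  list(overlap = a, odds_ratio = (cells[1] * cells[4]) / (cells[2] * cells[3]),
       p = p)
}

#' GSEA enrichment score with running sums and leading edge
#'
#' Weighted Kolmogorov-Smirnov-like statistic over a ranked gene list:
#' \eqn{P_{hit}(i)} accumulates \eqn{|r_j|^p / N_R} over set members up to
#' position i, \eqn{P_{miss}(i)} accumulates \eqn{1/(N - N_H)} over
#' non-members; ES is the signed maximum deviation of
#' \eqn{P_{hit} - P_{miss}}. Leading-edge genes are the set members at or
#' before the peak (positive ES) or at or after it (negative ES).
#' Exponent \code{p = 0} reduces to the classic rank KS statistic.
#'
#' @param genes Ranked gene ids (best first), unique.
#' @param scores Ranking scores \eqn{r_j} parallel to \code{genes}.
#' @param set Character vector, the gene set.
#' @param p Weight exponent (default 1).
#' @return List: \code{ES}, \code{peak} (position), \code{leading_edge},
#'   \code{P_hit}, \code{P_miss}, \code{N_H}, \code{N_R}.
#' @export
gseaES <- function(genes, scores, set, p = 1) {
  stopifnot(length(genes) == length(scores))
  if (anyDuplicated(genes)) stop("ranked list must have unique genes")
  N <- length(genes)
  hit <- genes %in% set
  N_H <- sum(hit)
  if (N_H == 0L) stop("gene set has no members in the ranked list")
  if (N_H == N) stop("gene set covers the whole list: P_miss undefined")
  w <- abs(scores)^p
  N_R <- sum(w[hit])
  if (N_R == 0) stop("all hit weights are zero")
  P_hit <- cumsum(ifelse(hit, w, 0)) / N_R
  P_miss <- cumsum(!hit) / (N - N_H)
  run <- P_hit - P_miss
  peak <- which.max(abs(run))
  ES <- run[peak]
  le <- if (ES >= 0) genes[hit & seq_len(N) <= peak]
        else genes[hit & seq_len(N) >= peak]
  list(ES = ES, peak = peak, leading_edge = le,
       P_hit = P_hit, P_miss = P_miss, N_H = N_H, N_R = N_R)
}

#' GSEA permutation p-value
#'
#' Gene-set permutation null: random sets of the same size drawn from the
#' ranked list; \eqn{p = (1 + \#\{|ES_{null}| \ge |ES_{obs}|\}) /
#' (n_{perm} + 1)}.
#'
#' @inheritParams gseaES
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed for the permutation stream.
#' @return List with \code{ES}, \code{p}, \code{n_perm},
#'   \code{leading_edge}.
#' @export
gseaPermutationP <- function(genes, scores, set, p = 1, n_perm = 1000L,
                             seed = 1L) {
  if (n_perm < 100L) stop("n_perm must be >= 100")
  obs <- gseaES(genes, scores, set, p)
  size <- obs$N_H
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    null_set <- sample(genes, size)
    es_b <- gseaES(genes, scores, null_set, p)$ES
    if (abs(es_b) >= abs(obs$ES)) exceed <- exceed + 1L
  }
  list(ES = obs$ES, p = (1 + exceed) / (n_perm + 1), n_perm = n_perm,
       leading_edge = obs$leading_edge)
}

#' Single-sample GSEA score
#'
#' Genes are ranked by expression (descending, average ranks on ties,
#' residual ties broken by gene id); the score is the summed difference of
#' the weighted in-set empirical CDF (rank weights
#' \eqn{|\mathrm{rank}|^\alpha}) and the uniform out-of-set ECDF over all
#' list positions. With \code{alpha = 0} the score depends on ranks only
#' and is invariant under monotone transforms of the expression vector.
#'
#' @param expr Named numeric vector: one sample's expression values.
#' @param set Character vector, the gene set.
#' @param alpha Rank weight exponent (default 0.25).
#' @return Numeric enrichment score.
#' @export
ssgseaScore <- function(expr, set, alpha = 0.25) {
  stopifnot(!is.null(names(expr)))
  N <- length(expr)
  hitgenes <- intersect(names(expr), set)
  if (length(hitgenes) == 0L) stop("gene set has no members in the sample")
  if (length(hitgenes) == N) stop("gene set covers all measured genes")
  rk <- rank(expr, ties.method = "average")   # rank N = highest expression
  ord <- order(-rk, names(expr))
  hit <- names(expr)[ord] %in% set
  w <- rk[ord]^alpha
  P_W <- cumsum(ifelse(hit, w, 0)) / sum(w[hit])
  P_NW <- cumsum(!hit) / (N - sum(hit))
  sum(P_W - P_NW)
}

#' ssGSEA score matrix
#'
#' Scores every (gene set, sample) pair; sets without any gene in the
#' matrix are dropped with a warning.
#'
#' @param m Gene-by-sample expression matrix.
#' @param collection A \linkS4class{GeneSetCollection}.
#' @param alpha Rank weight exponent.
#' @param normalize Min-max normalize the final matrix by the global score
#'   range (off by default; raw sums reported).
#' @return Pathway-by-sample numeric matrix.
#' @export
ssgseaMatrix <- function(m, collection, alpha = 0.25, normalize = FALSE) {
  stopifnot(is.matrix(m), is(collection, "GeneSetCollection"))
  if (length(collection) == 0L) stop("empty gene set collection")
  measured <- toupper(rownames(m))
  usable <- vapply(geneSets(collection),
                   function(s) any(s %in% measured) && !all(measured %in% s),
                   logical(1))
  if (!all(usable))
    warning("dropping ", sum(!usable), " set(s) with no measured genes")
  sets <- geneSets(collection)[usable]
  out <- matrix(NA_real_, length(sets), ncol(m),
                dimnames = list(names(sets), colnames(m)))
  for (j in seq_len(ncol(m))) {
    v <- stats::setNames(m[, j], measured)
    for (i in seq_along(sets))
      out[i, j] <- ssgseaScore(v, sets[[i]], alpha)
  }
  if (normalize) out <- out / (max(out) - min(out))
  out
}

#' Enrichment map of gene-set overlaps
#'
#' Gene sets become nodes (annotated with size and an optional enrichment
#' score); two sets are connected iff their Jaccard similarity strictly
#' exceeds the threshold, with the coefficient as edge weight.
#'
#' @param collection A \linkS4class{GeneSetCollection}.
#' @param node_scores Optional named numeric vector of per-set scores.
#' @param threshold Jaccard threshold; an edge needs similarity
#'   \emph{strictly greater} than this (default 0.25).
#' @return Undirected \code{igraph} with vertex attributes \code{size},
#'   \code{score} and edge attribute \code{jaccard}.
#' @export
enrichmentMap <- function(collection, node_scores = NULL, threshold = 0.25) {
  stopifnot(is(collection, "GeneSetCollection"), length(collection) > 0)
  sets <- geneSets(collection)
  nms <- names(sets)
  n <- length(sets)
  edges <- character(0); jac <- numeric(0)
  if (n >= 2) for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    J <- length(intersect(sets[[i]], sets[[j]])) /
         length(union(sets[[i]], sets[[j]]))
    if (J > threshold) {
      edges <- c(edges, nms[i], nms[j])
      jac <- c(jac, J)
    }
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, n, name = nms, size = lengths(sets),
                            score = if (is.null(node_scores)) NA_real_
                                    else as.numeric(node_scores[nms]))
  if (length(jac))
    g <- igraph::add_edges(g, match(edges, nms), jaccard = jac)
  g
}
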