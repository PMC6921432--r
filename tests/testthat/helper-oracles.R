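# Independent brute-force oracles used across the suite. These never call
# package code paths: distances by hand-rolled BFS, betweenness by explicit
# shortest-path enumeration, Fisher tails by direct hypergeometric sums.

# adjacency list (by index) from an igraph, chosen orientation
adjList <- function(g, mode = "all") {
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  adj <- vector("list", n)
  addE <- function(adj, from, to) {
    for (i in seq_len(nrow(el))) adj[[el[i, from]]] <- c(adj[[el[i, from]]], el[i, to])
    adj
  }
  if (mode %in% c("all", "out")) adj <- addE(adj, 1, 2)
  if (mode %in% c("all", "in")) adj <- addE(adj, 2, 1)
  lapply(adj, unique)
}

bfsDist <- function(adj, start) {
  n <- length(adj)
  dist <- rep(Inf, n)
  dist[start] <- 0
  frontier <- start
  d <- 0
  while (length(frontier)) {
    d <- d + 1
    nxt <- unique(unlist(adj[frontier]))
    nxt <- nxt[is.infinite(dist[nxt])]
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

# all shortest paths s -> t by depth-limited DFS; returns list of vertex seqs
allShortestPaths <- function(adj, s, t, len) {
  if (s == t) return(list(s))
  if (len == 0) return(list())
  out <- list()
  for (v in adj[[s]]) {
    for (p in allShortestPaths(adj, v, t, len - 1))
      out[[length(out) + 1]] <- c(s, p)
  }
  out
}

bruteCentralities <- function(g) {
  n <- igraph::vcount(g)
  adj <- adjList(g, "all")
  D <- t(vapply(seq_len(n), function(s) bfsDist(adj, s), numeric(n)))
  deg <- lengths(adj)
  harm <- vapply(seq_len(n), function(v) {
    d <- D[v, -v]
    sum(1 / d[is.finite(d)])
  }, numeric(1))
  btw <- numeric(n)
  if (n >= 3) for (s in 1:(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(D[s, t])) next
    paths <- allShortestPaths(adj, s, t, D[s, t])
    paths <- Filter(function(p) length(p) == D[s, t] + 1, paths)
    if (!length(paths)) next
    for (v in setdiff(seq_len(n), c(s, t))) {
      frac <- mean(vapply(paths, function(p) v %in% p, logical(1)))
      btw[v] <- btw[v] + frac
    }
  }
  list(degree = deg, closeness = harm, betweenness = btw,
       dist = D)
}

bruteLCCSize <- function(g) {
  adj <- adjList(g, "all")
  n <- length(adj)
  best <- 0
  for (s in seq_len(n)) {
    comp <- sum(is.finite(bfsDist(adj, s)))
    best <- max(best, comp)
  }
  best
}

# one-sided (greater) hypergeometric tail by direct summation
bruteFisherGreater <- function(a, n_query, n_target, n_universe) {
  jmax <- min(n_query, n_target)
  if (a > jmax) return(0)
  js <- a:jmax
  sum(choose(n_target, js) * choose(n_universe - n_target, n_query - js)) /
    choose(n_universe, n_query)
}

# exhaustive KDA oracle on a small directed graph: for every node, every
# layer depth, the downstream neighborhood from hand BFS and the Fisher
# tail from bruteFisherGreater; returns the per-node minimal p and h*
bruteKDA <- function(g, G, H) {
  nodes <- igraph::V(g)$name
  n <- length(nodes)
  adj_out <- adjList(g, "out")
  adj_all <- adjList(g, "all")
  Gp <- intersect(G, nodes)
  gi <- match(Gp, nodes)
  # NG: nodes within H layers of G in either orientation
  inNG <- rep(FALSE, n)
  for (s in gi) inNG[bfsDist(adj_all, s) <= H] <- TRUE
  res <- lapply(which(inNG), function(v) {
    Gx <- setdiff(gi, v)
    dist <- bfsDist(adj_out, v)
    best_p <- Inf; best_h <- NA
    for (h in seq_len(H)) {
      hln <- which(dist >= 1 & dist <= h)
      a <- length(intersect(hln, Gx))
      p <- bruteFisherGreater(a, length(hln), length(Gx), n - 1)
      if (p < best_p) { best_p <- p; best_h <- h }
    }
    data.frame(gene = nodes[v], p = best_p, h_star = best_h,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- pmin(1, out$p * sum(inNG))
  out[order(out$gene), ]
}

# random simple undirected graph as igraph, n nodes, edge prob p
randomGraph <- function(n, p) {
  m <- matrix(0L, n, n)
  m[upper.tri(m)] <- stats::rbinom(n * (n - 1) / 2, 1, p)
  g <- igraph::graph_from_adjacency_matrix(m + t(m), mode = "undirected")
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  g
}

# random DAG: fixed topological order, forward edges with prob p
randomDAG <- function(n, p) {
  m <- matrix(0L, n, n)
  m[upper.tri(m)] <- stats::rbinom(n * (n - 1) / 2, 1, p)
  g <- igraph::graph_from_adjacency_matrix(m, mode = "directed")
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  g
}

# Rand index between two labelings
randIndex <- function(a, b) {
  n <- length(a)
  agree <- 0; total <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    total <- total + 1
    if ((a[i] == a[j]) == (b[i] == b[j])) agree <- agree + 1
  }
  agree / total
}

# small two-cluster pathway-score matrix: features x samples, the first
# n_active features shifted by delta in cluster 2. Defaults emulate a
# pathway panel where most members separate the two subgroups (as in
# clearly stratified cohorts), so cluster recovery is attainable.
plantedScoreMatrix <- function(n_feat = 26, n_samp = 30, n_active = 20,
                               delta = 2, sd = 1) {
  m <- matrix(stats::rnorm(n_feat * n_samp, sd = sd), n_feat, n_samp)
  cl <- rep(1:2, length.out = n_samp)
  m[seq_len(n_active), cl == 2] <- m[seq_len(n_active), cl == 2] + delta
  dimnames(m) <- list(sprintf("PW%02d", seq_len(n_feat)),
                      sprintf("S%03d", seq_len(n_samp)))
  list(scores = m, labels = cl)
}
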