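#' Agglomerative hierarchical clustering (UPGMA, Euclidean)
#'
#' @param x Samples-by-features numeric matrix.
#' @param k Number of clusters to cut to (k <= n).
#' @return Integer cluster labels named by sample. The \code{hclust} merge
#'   record is attached as attribute \code{"hclust"}.
#' @export
hierCluster <- function(x, k) {
  stopifnot(is.matrix(x), all(is.finite(x)))
  if (k > nrow(x)) stop("k exceeds the number of samples")
  hc <- stats::hclust(stats::dist(x, method = "euclidean"),
                      method = "average")
  labels <- stats::cutree(hc, k = k)
  names(labels) <- rownames(x)
  attr(labels, "hclust") <- hc
  labels
}

#' Mean silhouette width
#'
#' Mean over samples of \eqn{(b - a)/\max(a, b)} where a is the mean
#' within-cluster distance and b the smallest mean distance to another
#' cluster; singleton clusters contribute 0.
#'
#' @param x Samples-by-features matrix.
#' @param labels Cluster labels (>= 2 distinct clusters).
#' @return Mean silhouette width.
#' @export
silhouetteScore <- function(x, labels) {
  if (length(unique(labels)) < 2L)
    stop("silhouette needs >= 2 clusters")
  sil <- cluster::silhouette(as.integer(factor(labels)),
                             stats::dist(x, method = "euclidean"))
  mean(sil[, "sil_width"])
}

#' Gap statistic for cluster-number selection
#'
#' Tibshirani gap statistic with uniform reference data over the
#' PCA-aligned bounding box: \eqn{Gap(k) = mean_b \log W^*_{kb} - \log W_k},
#' \eqn{s_k = sd_b \sqrt{1 + 1/B}}. The chosen k is the smallest k in the
#' searched range with \eqn{Gap(k) \ge Gap(k+1) - s_{k+1}} (the last k if
#' never satisfied). Clustering is UPGMA on Euclidean distances throughout.
#'
#' @param x Samples-by-features matrix.
#' @param k_range Integer range of cluster numbers to search (default 2:5).
#' @param B Number of reference datasets (>= 10).
#' @param seed Integer seed for the reference draws.
#' @return List: \code{k} (chosen), \code{gap}, \code{se} (per searched k),
#'   and the full \code{clusGap} table as \code{tab}.
#' @export
gapStatistic <- function(x, k_range = 2:5, B = 50L, seed = 1L) {
  if (B < 10L) stop("B must be >= 10")
  stopifnot(is.matrix(x), max(k_range) <= nrow(x) - 1L)
  hclustCut <- function(x, k)
    list(cluster = stats::cutree(stats::hclust(stats::dist(x), "average"), k))
  set.seed(seed)
  cg <- cluster::clusGap(x, FUNcluster = hclustCut, K.max = max(k_range),
                         B = B, spaceH0 = "scaledPCA", verbose = FALSE)
  tab <- cg$Tab
  ks <- sort(unique(as.integer(k_range)))
  gap <- tab[ks, "gap"]; se <- tab[ks, "SE.sim"]
  chosen <- ks[length(ks)]
  for (i in seq_len(length(ks) - 1L)) {
    if (gap[i] >= gap[i + 1L] - se[i + 1L]) { chosen <- ks[i]; break }
  }
  list(k = chosen, gap = stats::setNames(gap, ks),
       se = stats::setNames(se, ks), tab = tab)
}

#' Pathway-score-driven subgrouping
#'
#' Transposes a pathway-by-sample enrichment score matrix to
#' samples-by-pathways, z-scores each pathway so none dominates by scale,
#' selects the cluster number by gap statistic (with mean silhouette
#' reported per k), and cuts the UPGMA tree.
#'
#' @param scores Pathway-by-sample enrichment score matrix.
#' @param k_range Cluster numbers searched (default 2:5).
#' @param B Gap-statistic reference draws.
#' @param seed Integer seed.
#' @return List: \code{k}, \code{labels} (named by sample),
#'   \code{silhouette} (per searched k), \code{gap} (gap-statistic
#'   report), \code{hclust}.
#' @export
clusterSubgroups <- function(scores, k_range = 2:5, B = 50L, seed = 1L) {
  x <- t(scores)
  sds <- apply(x, 2, stats::sd)
  x <- scale(x, center = TRUE, scale = ifelse(sds > 0, sds, 1))
  gap <- gapStatistic(x, k_range = k_range, B = B, seed = seed)
  sil <- vapply(k_range, function(k)
    silhouetteScore(x, hierCluster(x, k)), numeric(1))
  labels <- hierCluster(x, gap$k)
  list(k = gap$k, labels = stats::setNames(as.integer(labels), rownames(x)),
       silhouette = stats::setNames(sil, k_range), gap = gap,
       hclust = attr(labels, "hclust"))
}

#' Between-cluster feature tests
#'
#' Per-feature two-sided comparison of exactly two clusters by unpaired t
#' test or Mann-Whitney U, with BH adjustment.
#'
#' @param scores Feature-by-sample matrix.
#' @param labels Two-level cluster labels named by (or ordered as) the
#'   samples.
#' @param method "t" or "mannwhitney".
#' @return \code{data.frame}: feature, statistic, p, adjP.
#' @export
betweenClusterTests <- function(scores, labels, method = c("t", "mannwhitney")) {
  method <- match.arg(method)
  if (!is.null(names(labels))) labels <- labels[colnames(scores)]
  lv <- unique(labels)
  if (length(lv) != 2L) stop("exactly 2 clusters required")
  g1 <- labels == lv[1]; g2 <- labels == lv[2]
  if (method == "t" && (sum(g1) < 2L || sum(g2) < 2L))
    stop("each cluster needs >= 2 samples for the t test")
  res <- t(apply(scores, 1, function(v) {
    ht <- if (method == "t") stats::t.test(v[g1], v[g2])
          else stats::wilcox.test(v[g1], v[g2], exact = FALSE)
    c(ht$statistic, ht$p.value)
  }))
  data.frame(feature = rownames(scores), statistic = res[, 1], p = res[, 2],
             adjP = bhAdjust(res[, 2]), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Paired pre/post feature tests
#'
#' Per-feature two-sided paired t test of matched sample pairs (e.g. two
#' timepoints). Degenerate all-zero differences give t = 0, p = 1.
#'
#' @param pre,post Feature-by-sample matrices with identical features and
#'   paired columns in matching order.
#' @return \code{data.frame}: feature, t, p, adjP.
#' @export
pairedChangeTests <- function(pre, post) {
  stopifnot(is.matrix(pre), is.matrix(post))
  if (!identical(dim(pre), dim(post)) ||
      !identical(rownames(pre), rownames(post)))
    stop("pre/post matrices must be feature-aligned with complete pairs")
  res <- t(vapply(seq_len(nrow(pre)), function(i) {
    d <- post[i, ] - pre[i, ]
    if (stats::sd(d) < 1e-15) {
      if (abs(mean(d)) < 1e-15) c(0, 1) else c(Inf * sign(mean(d)), 0)
    } else {
      ht <- stats::t.test(d)
      c(unname(ht$statistic), ht$p.value)
    }
  }, numeric(2)))
  data.frame(feature = rownames(pre), t = res[, 1], p = res[, 2],
             adjP = bhAdjust(res[, 2]), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Association tests between sample-level variables
#'
#' Categorical vs categorical: chi-squared with expected-count check,
#' falling back to Fisher's exact test when any expected cell count is
#' below 5. Continuous vs continuous: Pearson correlation with t-based p.
#'
#' @param a,b Categorical vectors (factors/characters) of equal length, or
#' @param x,y numeric vectors of equal length.
#' @return List with \code{method} and \code{p} (categorical) or
#'   \code{r} and \code{p} (continuous).
#' @export
associationTests <- function(a = NULL, b = NULL, x = NULL, y = NULL) {
  if (!is.null(a) && !is.null(b)) {
    stopifnot(length(a) == length(b))
    tb <- table(a, b)
    suppressWarnings(ct <- stats::chisq.test(tb, correct = FALSE))
    if (any(ct$expected < 5)) {
      ft <- stats::fisher.test(tb)
      return(list(method = "fisher", p = ft$p.value))
    }
    return(list(method = "chisq", p = ct$p.value))
  }
  if (!is.null(x) && !is.null(y)) {
    stopifnot(length(x) == length(y))
    if (stats::sd(x) < 1e-15 || stats::sd(y) < 1e-15)
      stop("constant vector: correlation undefined")
    ct <- stats::cor.test(x, y, method = "pearson")
    return(list(method = "pearson", r = unname(ct$estimate), p = ct$p.value))
  }
  stop("supply either (a, b) categorical or (x, y) numeric")
}
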