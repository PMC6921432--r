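#' Fit per-gene two-group linear models
#'
#' For each gene, the case/control contrast: log2 fold change = mean(case)
#' - mean(control), pooled residual variance, and residual degrees of
#' freedom n - 2.
#'
#' @param m Gene-by-sample log2 matrix.
#' @param annotation Sample annotation with \code{sample_id} and
#'   \code{group} in \{"case", "control"\}; both groups need >= 2 samples.
#' @return List with \code{logFC}, \code{s2} (pooled residual variance),
#'   \code{df} (residual df, scalar), \code{n1}, \code{n2}, \code{genes}.
#' @export
fitGeneModels <- function(m, annotation) {
  stopifnot(is.matrix(m))
  ann <- annotation[match(colnames(m), annotation$sample_id), , drop = FALSE]
  case <- ann$group == "case"
  ctrl <- ann$group == "control"
  n1 <- sum(case); n2 <- sum(ctrl)
  if (n1 < 2L || n2 < 2L)
    stop("both groups need >= 2 samples")
  mu1 <- rowMeans(m[, case, drop = FALSE])
  mu2 <- rowMeans(m[, ctrl, drop = FALSE])
  rss <- rowSums((m[, case, drop = FALSE] - mu1)^2) +
         rowSums((m[, ctrl, drop = FALSE] - mu2)^2)
  df <- n1 + n2 - 2L
  list(logFC = mu1 - mu2, s2 = rss / df, df = df,
       n1 = n1, n2 = n2, genes = rownames(m))
}

#' Estimate empirical-Bayes variance prior by method of moments
#'
#' Estimates the prior degrees of freedom \code{d0} and prior variance
#' \code{s0_sq} of the scaled inverse-chi-squared variance prior from the
#' marginal distribution of log sample variances: with
#' \eqn{e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)}, solve
#' \eqn{\psi'(d_0/2) = \mathrm{mean}\{(e_g-\bar e)^2 G/(G-1) - \psi'(d_g/2)\}}
#' by monotone root-finding; a nonpositive right-hand side gives
#' \code{d0 = Inf} (no between-gene variance dispersion).
#'
#' @param s2 Per-gene residual variances (>= 10 genes with positive df).
#' @param df Residual degrees of freedom (scalar or per-gene).
#' @return List with \code{d0} and \code{s0_sq}.
#' @export
estimateEBParams <- function(s2, df) {
  if (all(s2 == 0)) stop("degenerate data: all residual variances are zero")
  df <- rep_len(df, length(s2))
  keep <- df > 0
  if (sum(keep) < 10L) stop("need >= 10 genes with positive residual df")
  s2 <- pmax(s2[keep], 1e-12)
  df <- df[keep]
  G <- length(s2)
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  rhs <- mean((e - ebar)^2 * G / (G - 1) - trigamma(df / 2))
  if (rhs <= 0)
    return(list(d0 = Inf, s0_sq = exp(ebar)))
  d0 <- 2 * trigammaInverse(rhs)
  list(d0 = d0, s0_sq = exp(ebar + digamma(d0 / 2) - log(d0 / 2)))
}

# Invert the trigamma function by Newton iteration (trigamma is positive,
# strictly decreasing and convex on (0, Inf), so the update converges
# monotonely from the starting value 0.5 + 1/x).
trigammaInverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (abs(dif) / y < 1e-10) break
  }
  y
}

#' Moderated t-statistics
#'
#' Shrinks each gene's variance toward the prior,
#' \eqn{\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)}, and tests the
#' log fold change with \eqn{\tilde t = \mathrm{logFC} /
#' \sqrt{\tilde s_g^2 (1/n_1 + 1/n_2)}} on \eqn{d_0 + d_g} degrees of
#' freedom (a normal reference in the \code{d0 = Inf} limit). \code{d0 = 0}
#' recovers the ordinary pooled-variance two-sample t exactly.
#'
#' @param fit Output of \code{\link{fitGeneModels}}.
#' @param eb List with \code{d0}, \code{s0_sq} (see
#'   \code{\link{estimateEBParams}}).
#' @return List with \code{t}, \code{df_total}, \code{p} (two-sided),
#'   \code{s2_post}.
#' @export
moderatedT <- function(fit, eb) {
  stopifnot(eb$d0 >= 0, eb$s0_sq > 0)
  s2_post <- if (is.infinite(eb$d0)) rep_len(eb$s0_sq, length(fit$s2))
             else (eb$d0 * eb$s0_sq + fit$df * fit$s2) / (eb$d0 + fit$df)
  zero <- s2_post < 1e-12
  if (any(zero)) {
    warning(sum(zero), " gene(s) with zero posterior variance; floored")
    s2_post[zero] <- 1e-12
  }
  se <- sqrt(s2_post * (1 / fit$n1 + 1 / fit$n2))
  tt <- fit$logFC / se
  df_total <- eb$d0 + fit$df
  p <- 2 * stats::pt(-abs(tt), df = df_total)
  list(t = tt, df_total = df_total, p = p, s2_post = s2_post)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' capped at 1.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values in the input order.
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE) || anyNA(p))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Differential-expression table
#'
#' Runs the full moderated-t workflow (per-gene linear models,
#' empirical-Bayes variance shrinkage, two-sided tests, BH adjustment) and
#' assembles the per-gene result table.
#'
#' @param m Normalized gene-by-sample matrix.
#' @param annotation Sample annotation (group in \{"case", "control"\}).
#' @return \code{data.frame} with gene, logFC, t, df_total, p, adjP,
#'   direction ("up"/"down"), in input gene order. The fitted EB parameters
#'   are attached as attribute \code{"eb"}.
#' @export
runDGE <- function(m, annotation) {
  fit <- fitGeneModels(m, annotation)
  eb <- estimateEBParams(fit$s2, fit$df)
  mt <- moderatedT(fit, eb)
  tab <- data.frame(gene = fit$genes, logFC = fit$logFC, t = mt$t,
                    df_total = mt$df_total, p = mt$p,
                    adjP = bhAdjust(mt$p),
                    direction = ifelse(fit$logFC >= 0, "up", "down"),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(tab, "eb") <- eb
  tab
}

#' Select differentially expressed genes
#'
#' @param tab DEG table from \code{\link{runDGE}}.
#' @param alpha Adjusted-p cutoff (default 0.01).
#' @param direction "up", "down" or "both".
#' @return Character vector of gene ids passing the filter, sorted by
#'   adjusted p then gene id.
#' @export
selectDEGs <- function(tab, alpha = 0.01, direction = c("up", "down", "both")) {
  direction <- match.arg(direction)
  if (nrow(tab) == 0L) return(character(0))
  keep <- tab$adjP < alpha
  if (direction != "both") keep <- keep & tab$direction == direction
  sel <- tab[keep, , drop = FALSE]
  sel$gene[order(sel$adjP, sel$gene)]
}
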