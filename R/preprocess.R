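#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) to share the identical empirical
#' distribution: each column's sorted values are replaced by the row-wise
#' mean of the column-sorted matrix. Tied values within a column receive the
#' mean of the reference values over their rank span. Idempotent.
#'
#' @param m Numeric gene-by-sample matrix, no missing values.
#' @return Matrix of the same shape with identical column distributions.
#' @export
quantileNormalize <- function(m) {
  stopifnot(is.matrix(m))
  if (ncol(m) < 2L)
    stop("quantile normalization needs >= 2 samples")
  if (any(!is.finite(m)))
    stop("expression matrix contains non-finite values")
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

varianceFloor <- 1e-8

#' Empirical-Bayes batch correction (parametric location-scale)
#'
#' Removes additive/multiplicative batch effects with the parametric
#' empirical-Bayes location-scale model: per-gene standardization with the
#' case/control factor protected in the design, per-batch location
#' (\eqn{\hat\gamma}) and scale (\eqn{\hat\delta^2}) estimates shrunk
#' toward batch-level prior moments (normal prior for location,
#' inverse-gamma via method of moments for scale), then back-transformation.
#' In \code{mean-only} mode the scale adjustment is skipped
#' (\eqn{\delta^{2*} \equiv 1}).
#'
#' @param m Gene-by-sample log2 matrix.
#' @param annotation Data.frame with \code{sample_id}, \code{batch},
#'   \code{group} matching the columns of \code{m}.
#' @param mode \code{"location-scale"} (default) or \code{"mean-only"}.
#'   Mean-only removes the raw per-batch location estimate without
#'   shrinkage and leaves scale untouched, so per-gene batch means
#'   equalize exactly.
#' @return List with \code{corrected} (matrix) and \code{model} (a
#'   \code{BatchModel} list: per-batch gamma_hat/delta_hat, shrunk
#'   gamma_star/delta_star, prior moments, pooled variance, mode).
#' @export
combatAdjust <- function(m, annotation, mode = c("location-scale", "mean-only")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(m))
  ann <- annotation[match(colnames(m), annotation$sample_id), , drop = FALSE]
  if (anyNA(ann$sample_id))
    stop("annotation does not cover all samples")
  batch <- factor(ann$batch)
  if (nlevels(batch) < 2L) {
    warning("single batch: no batch term to remove, returning input")
    return(list(corrected = m, model = NULL))
  }
  if (any(table(batch) < 2L))
    stop("every batch needs >= 2 samples for batch correction")
  group <- factor(ann$group)
  n <- ncol(m); G <- nrow(m); nb <- nlevels(batch)

  B <- stats::model.matrix(~ 0 + batch)
  Z <- if (nlevels(group) >= 2L)
    stats::model.matrix(~ group)[, -1, drop = FALSE] else NULL
  X <- cbind(B, Z)
  beta <- solve(crossprod(X), crossprod(X, t(m)))       # p x G
  batch_frac <- as.numeric(table(batch)) / n
  grand_mean <- as.numeric(crossprod(batch_frac, beta[seq_len(nb), , drop = FALSE]))
  stand_mean <- matrix(grand_mean, G, n)
  if (!is.null(Z))
    stand_mean <- stand_mean +
      t(Z %*% beta[-seq_len(nb), , drop = FALSE])
  resid <- m - t(X %*% beta)
  var_pooled <- rowSums(resid^2) / n
  floored <- var_pooled < varianceFloor
  if (any(floored)) {
    warning(sum(floored), " zero-variance gene(s); variance floored")
    var_pooled[floored] <- varianceFloor
  }
  s_data <- (m - stand_mean) / sqrt(var_pooled)

  gamma_hat <- delta_hat <- gamma_star <- delta_star <-
    matrix(NA_real_, G, nb, dimnames = list(rownames(m), levels(batch)))
  gamma_bar <- t2 <- a_prior <- b_prior <- numeric(nb)
  for (i in seq_len(nb)) {
    sel <- batch == levels(batch)[i]
    sd_i <- s_data[, sel, drop = FALSE]
    ni <- sum(sel)
    gamma_hat[, i] <- rowMeans(sd_i)
    delta_hat[, i] <- rowSums((sd_i - gamma_hat[, i])^2) / (ni - 1)
    gamma_bar[i] <- mean(gamma_hat[, i])
    t2[i] <- stats::var(gamma_hat[, i])
    md <- mean(delta_hat[, i]); vd <- stats::var(delta_hat[, i])
    a_prior[i] <- (2 * vd + md^2) / vd
    b_prior[i] <- (md * vd + md^3) / vd
    if (mode == "mean-only") {
      # plain per-gene location centering: the raw batch deviation is
      # removed exactly, so per-gene batch means equalize; no scale term
      gamma_star[, i] <- gamma_hat[, i]
      delta_star[, i] <- 1
    } else {
      fit <- ebIterate(sd_i, gamma_hat[, i], delta_hat[, i],
                       gamma_bar[i], t2[i], a_prior[i], b_prior[i])
      gamma_star[, i] <- fit$gamma
      delta_star[, i] <- fit$delta
    }
  }
  bi <- as.integer(batch)
  corrected <- (s_data - gamma_star[, bi]) / sqrt(delta_star[, bi]) *
    sqrt(var_pooled) + stand_mean
  dimnames(corrected) <- dimnames(m)
  model <- structure(list(gamma_hat = gamma_hat, delta_hat = delta_hat,
                          gamma_star = gamma_star, delta_star = delta_star,
                          gamma_bar = gamma_bar, t2 = t2,
                          a_prior = a_prior, b_prior = b_prior,
                          grand_mean = grand_mean, var_pooled = var_pooled,
                          mode = mode),
                     class = "BatchModel")
  list(corrected = corrected, model = model)
}

# Iterative solution of the EB posterior for one batch: conditional
# posterior means of gamma (normal prior) and delta^2 (inverse gamma),
# alternated to convergence.
ebIterate <- function(sdat, g_hat, d_hat, g_bar, t2, a, b, conv = 1e-6) {
  ni <- ncol(sdat)
  g_old <- g_hat; d_old <- d_hat
  for (iter in 1:200) {
    g_new <- (t2 * ni * g_hat + d_old * g_bar) / (t2 * ni + d_old)
    sum2 <- rowSums((sdat - g_new)^2)
    d_new <- (0.5 * sum2 + b) / (ni / 2 + a - 1)
    change <- max(abs(g_new - g_old) / (abs(g_old) + 1e-12),
                  abs(d_new - d_old) / d_old)
    g_old <- g_new; d_old <- d_new
    if (change < conv) break
  }
  list(gamma = g_new, delta = pmax(d_new, varianceFloor))
}

#' Principal component QC of batch and group structure
#'
#' PCA over samples with per-component variance explained and the R-squared
#' of batch and group factors on each component score; pure reporting.
#'
#' @param m Gene-by-sample matrix.
#' @param annotation Sample annotation (batch, group).
#' @param k Number of components to report.
#' @return List with \code{scores} (samples x k), \code{var_explained},
#'   \code{batch_r2}, \code{group_r2}.
#' @export
pcaQC <- function(m, annotation, k = 5L) {
  stopifnot(is.matrix(m))
  if (ncol(m) < 3L) stop("PCA QC needs >= 3 samples")
  if (all(apply(m, 1, stats::sd) < 1e-12))
    stop("constant matrix: no variance to decompose")
  ann <- annotation[match(colnames(m), annotation$sample_id), , drop = FALSE]
  pc <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  k <- min(k, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  r2 <- function(fac) apply(scores, 2, function(s)
    summary(stats::lm(s ~ factor(fac)))$r.squared)
  list(scores = scores, var_explained = ve[seq_len(k)],
       batch_r2 = r2(ann$batch), group_r2 = r2(ann$group))
}
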