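test_that("quantile normalization matches the rank-mean construction", {
  m <- cbind(s1 = c(1, 2), s2 = c(3, 4))
  rownames(m) <- c("g1", "g2")
  out <- quantileNormalize(m)
  expect_equal(unname(out), cbind(c(2, 3), c(2, 3)))

  # defining property: identical column distributions, idempotence
  set.seed(1)
  m2 <- matrix(rnorm(600), 60, 10,
               dimnames = list(sprintf("g%02d", 1:60), sprintf("s%02d", 1:10)))
  q1 <- quantileNormalize(m2)
  ref <- unname(sort(q1[, 1]))
  for (j in 2:ncol(q1)) expect_equal(unname(sort(q1[, j])), ref)
  expect_equal(quantileNormalize(q1), q1, tolerance = 1e-12)

  # fixed point when all columns already identical
  m3 <- matrix(rep(c(5, 1, 3), 4), 3, 4,
               dimnames = list(c("a", "b", "c"), sprintf("s%d", 1:4)))
  expect_equal(quantileNormalize(m3), m3)

  expect_error(quantileNormalize(m2[, 1, drop = FALSE]), ">= 2 samples")
})

mkAnn <- function(n, batch, group) {
  data.frame(sample_id = sprintf("s%03d", seq_len(n)), batch = batch,
             group = group, stringsAsFactors = FALSE)
}

test_that("batch correction removes a planted constant shift (mean-only)", {
  set.seed(42)
  G <- 80; n <- 20
  base <- matrix(rnorm(G * n, mean = 7), G, n,
                 dimnames = list(sprintf("g%02d", 1:G), sprintf("s%03d", 1:n)))
  batch <- rep(c("B1", "B2"), each = n / 2)
  group <- rep(c("case", "control"), n / 2)
  shifted <- base
  shifted[, batch == "B2"] <- shifted[, batch == "B2"] + 1.5
  ann <- mkAnn(n, batch, group)
  res <- combatAdjust(shifted, ann, mode = "mean-only")
  bm1 <- rowMeans(res$corrected[, batch == "B1"])
  bm2 <- rowMeans(res$corrected[, batch == "B2"])
  expect_lt(max(abs(bm1 - bm2)), 1e-6)
  # corrected data recover the pre-shift matrix up to the per-gene centering
  # constant: residual variation per gene far below the planted 1.5 shift
  resid <- res$corrected - base
  expect_lt(mean(apply(resid, 1, sd)), 0.4)
  expect_true(all(res$model$delta_star == 1))
})

test_that("single batch is a pass-through and tiny batches error", {
  set.seed(1)
  m <- matrix(rnorm(40), 10, 4,
              dimnames = list(sprintf("g%d", 1:10), sprintf("s%03d", 1:4)))
  ann1 <- mkAnn(4, rep("B1", 4), rep(c("case", "control"), 2))
  expect_warning(res <- combatAdjust(m, ann1), "single batch")
  expect_equal(res$corrected, m, tolerance = 1e-8)
  ann2 <- mkAnn(4, c("B1", "B1", "B1", "B2"), rep(c("case", "control"), 2))
  expect_error(combatAdjust(m, ann2), ">= 2 samples")
})

test_that("EB shrinkage keeps batch estimates between raw and prior", {
  set.seed(3)
  ex <- generateExpression(syntheticConfig(
    n_genes = 300L, n_samples_per_group = c(case = 10L, control = 10L),
    n_batches = 2L, n_de_genes = 30L, batch_shift_sd = 0.5, seed = 3L))
  res <- combatAdjust(ex$expr, ex$annotation)
  md <- res$model
  for (i in seq_len(ncol(md$gamma_hat))) {
    lo <- pmin(md$gamma_hat[, i], md$gamma_bar[i]) - 1e-8
    hi <- pmax(md$gamma_hat[, i], md$gamma_bar[i]) + 1e-8
    expect_true(all(md$gamma_star[, i] >= lo & md$gamma_star[, i] <= hi))
  }
  expect_true(all(md$delta_star > 0))
})

test_that("correction reduces batch structure but preserves the DE signal", {
  cfg <- syntheticConfig(n_genes = 500L,
                         n_samples_per_group = c(case = 15L, control = 15L),
                         n_batches = 3L, n_de_genes = 50L, de_effect = 1.5,
                         batch_shift_sd = 1, cluster_shift = 0, seed = 11L)
  ex <- generateExpression(cfg)
  res <- combatAdjust(ex$expr, ex$annotation)
  qc_pre <- pcaQC(ex$expr, ex$annotation)
  qc_post <- pcaQC(res$corrected, ex$annotation)
  expect_lt(qc_post$batch_r2[1], qc_pre$batch_r2[1])

  case <- ex$annotation$group == "case"
  fc_pre <- rowMeans(ex$expr[, case]) - rowMeans(ex$expr[, !case])
  fc_post <- rowMeans(res$corrected[, case]) - rowMeans(res$corrected[, !case])
  expect_gt(cor(fc_pre, fc_post), 0.95)
})

test_that("location-scale correction agrees with the reference ComBat", {
  skip_if_not_installed("sva")
  cfg <- syntheticConfig(n_genes = 200L,
                         n_samples_per_group = c(case = 8L, control = 8L),
                         n_batches = 2L, n_de_genes = 20L,
                         batch_shift_sd = 0.8, cluster_shift = 0, seed = 5L)
  ex <- generateExpression(cfg)
  ours <- combatAdjust(ex$expr, ex$annotation)$corrected
  mod <- stats::model.matrix(~ group, data = ex$annotation)
  ref <- suppressMessages(
    sva::ComBat(ex$expr, batch = ex$annotation$batch, mod = mod,
                par.prior = TRUE, prior.plots = FALSE))
  expect_gt(cor(as.vector(ours), as.vector(ref)), 0.999)
  expect_lt(mean(abs(ours - ref)), 0.05)
})

test_that("PCA QC reports orthogonal scores and a dominant first axis", {
  set.seed(2)
  n <- 12
  lat <- rnorm(n, sd = 4)
  m <- rbind(outer(rep(1, 30), lat) + matrix(rnorm(30 * n, sd = 0.1), 30, n),
             matrix(rnorm(20 * n, sd = 0.1), 20, n))
  dimnames(m) <- list(sprintf("g%02d", 1:50), sprintf("s%03d", 1:n))
  ann <- mkAnn(n, rep(c("B1", "B2"), 6), rep(c("case", "control"), each = 6))
  qc <- pcaQC(m, ann)
  expect_true(all(qc$var_explained[1] >= qc$var_explained[-1]))
  cp <- crossprod(qc$scores)
  expect_lt(max(abs(cp[upper.tri(cp)])), 1e-8)
  expect_error(pcaQC(matrix(1, 5, 5,
                            dimnames = list(letters[1:5], LETTERS[1:5])),
                     mkAnn(5, rep("B1", 5), rep("case", 5))),
               "constant")
})
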