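mkExpr <- function(case, ctrl, genes = NULL) {
  m <- cbind(case, ctrl)
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(m)))
  dimnames(m) <- list(genes,
                      c(sprintf("ca%02d", seq_len(ncol(case))),
                        sprintf("co%02d", seq_len(ncol(ctrl)))))
  ann <- data.frame(sample_id = colnames(m),
                    batch = "B1",
                    group = rep(c("case", "control"),
                                c(ncol(case), ncol(ctrl))),
                    stringsAsFactors = FALSE)
  list(m = m, ann = ann)
}

test_that("per-gene linear models give hand-computed logFC and variances", {
  d <- mkExpr(case = rbind(c(2, 2), c(3, 1)), ctrl = rbind(c(1, 1), c(2, 0)))
  fit <- fitGeneModels(d$m, d$ann)
  expect_equal(unname(fit$logFC), c(1, 1))
  expect_equal(unname(fit$s2), c(0, 2))   # pooled: (var(3,1)+var(2,0))/2 scaled by df
  expect_identical(fit$df, 2L)

  # swapping labels negates every logFC
  ann2 <- d$ann
  ann2$group <- ifelse(ann2$group == "case", "control", "case")
  expect_equal(fitGeneModels(d$m, ann2)$logFC, -fit$logFC)

  expect_error(fitGeneModels(d$m[, c(1, 3, 4), drop = FALSE],
                             d$ann[c(1, 3, 4), ]), ">= 2 samples")
})

test_that("EB prior estimation recovers simulated hyperparameters", {
  # identical variances with large df: no dispersion left, d0 -> Inf
  eb0 <- estimateEBParams(rep(2, 100), 50)
  expect_true(is.infinite(eb0$d0))
  expect_equal(eb0$s0_sq, 2, tolerance = 0.05)

  # scaled inverse-chi-square prior with d0 = 4, s0 = 2, sampling df = 8
  set.seed(99)
  G <- 5000; d0_true <- 4; s0_true <- 2; dg <- 8
  sigma2 <- d0_true * s0_true / rchisq(G, d0_true)
  s2 <- sigma2 * rchisq(G, dg) / dg
  eb <- estimateEBParams(s2, dg)
  expect_lt(abs(eb$d0 - d0_true) / d0_true, 0.25)
  expect_lt(abs(eb$s0_sq - s0_true) / s0_true, 0.15)

  expect_error(estimateEBParams(rep(0, 50), 8), "degenerate")
})

test_that("moderated variance is a shrinkage between s2 and the prior", {
  eb <- list(d0 = 4, s0_sq = 1)
  fit <- list(logFC = c(1, 1, 1), s2 = c(0.25, 1, 4), df = 8,
              n1 = 5, n2 = 5, genes = c("a", "b", "c"))
  mt <- moderatedT(fit, eb)
  expect_equal(mt$s2_post[2], 1)    # fixed point at s2 = s0
  expect_true(all(abs(mt$s2_post - eb$s0_sq) <= abs(fit$s2 - eb$s0_sq) + 1e-12))
})

test_that("d0 = 0 recovers the ordinary pooled t; d0 = Inf is proportional to logFC", {
  set.seed(7)
  d <- mkExpr(case = matrix(rnorm(50 * 4, 1), 50, 4),
              ctrl = matrix(rnorm(50 * 4), 50, 4))
  fit <- fitGeneModels(d$m, d$ann)
  mt0 <- moderatedT(fit, list(d0 = 0, s0_sq = 1))
  # independent ordinary t per gene
  for (i in c(1, 17, 50)) {
    tt <- t.test(d$m[i, 1:4], d$m[i, 5:8], var.equal = TRUE)
    expect_equal(unname(mt0$t[i]), unname(tt$statistic), tolerance = 1e-10)
    expect_equal(unname(mt0$p[i]), tt$p.value, tolerance = 1e-10)
  }
  mtInf <- moderatedT(fit, list(d0 = Inf, s0_sq = 2))
  expect_equal(cor(mtInf$t, fit$logFC), 1, tolerance = 1e-12)
})

test_that("full moderated workflow agrees with the reference limma fit", {
  # heteroscedastic genes (scaled inverse-chi-square variances) so the
  # prior df estimate is finite and both implementations take the same path
  set.seed(12)
  G <- 500; n1 <- 8; n2 <- 8
  sigma2 <- 6 * 0.3 / rchisq(G, 6)
  m <- matrix(rnorm(G * (n1 + n2), mean = 7, sd = sqrt(sigma2)), G, n1 + n2)
  dimnames(m) <- list(sprintf("g%03d", 1:G),
                      sprintf("s%02d", 1:(n1 + n2)))
  ann <- data.frame(sample_id = colnames(m), batch = "B1",
                    group = rep(c("case", "control"), c(n1, n2)),
                    stringsAsFactors = FALSE)
  tab <- runDGE(m, ann)
  design <- stats::model.matrix(~ factor(ann$group,
                                         levels = c("control", "case")))
  lf <- limma::eBayes(limma::lmFit(m, design))
  expect_equal(tab$logFC, unname(lf$coefficients[, 2]), tolerance = 1e-10)
  expect_equal(attr(tab, "eb")$d0, lf$df.prior, tolerance = 1e-6)
  expect_equal(attr(tab, "eb")$s0_sq, lf$s2.prior, tolerance = 1e-6)
  expect_equal(tab$t, unname(lf$t[, 2]), tolerance = 1e-8)
  expect_equal(tab$p, unname(lf$p.value[, 2]), tolerance = 1e-8)
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(0.2), 0.2)
  expect_equal(bhAdjust(rep(0.4, 5)), rep(0.4, 5))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # permutation invariance (up to re-ordering)
  set.seed(5)
  p <- runif(40)
  perm <- sample(40)
  expect_equal(bhAdjust(p)[perm], bhAdjust(p[perm]))
})

test_that("DEG selection filters by adjusted p and direction", {
  tab <- data.frame(gene = c("a", "b", "c"), logFC = c(2, -1, 0.5),
                    t = 0, df_total = 10,
                    p = c(1e-4, 1e-4, 0.5),
                    adjP = c(0.005, 0.005, 0.6),
                    direction = c("up", "down", "up"),
                    stringsAsFactors = FALSE)
  expect_identical(selectDEGs(tab, 0.01, "up"), "a")
  expect_identical(selectDEGs(tab, 0.01, "down"), "b")
  expect_setequal(selectDEGs(tab, 0.01, "both"), c("a", "b"))
  expect_identical(selectDEGs(tab[0, ], 0.01, "up"), character(0))
})

test_that("planted upregulated genes are recovered with controlled FDR", {
  cfg <- syntheticConfig(n_genes = 2000L,
                         n_samples_per_group = c(case = 15L, control = 15L),
                         n_batches = 2L, batch_shift_sd = 0,
                         n_de_genes = 100L, de_effect = 2, de_prop_up = 1,
                         cluster_shift = 0, noise_sd = 0.5, seed = 21L)
  ex <- generateExpression(cfg)
  degs <- selectDEGs(runDGE(ex$expr, ex$annotation), alpha = 0.01, "up")
  planted <- names(ex$truth$de_genes)
  expect_gte(mean(planted %in% degs), 0.9)
  expect_lte(mean(!(degs %in% planted)), 0.05)
})
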