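#' Run the integrated stratification pipeline
#'
#' Executes the full analysis on a synthetic study (or user-supplied
#' inputs of the same shape): quantile normalization and batch correction
#' with PCA QC, moderated-t differential expression, projection of the
#' upregulated DEGs onto the interactome with LCC and hub analysis, ssGSEA
#' pathway scoring, pathway-driven case subgrouping with gap/silhouette
#' model selection, between-cluster tests, a naive Bayes subgroup
#' classifier with 10-fold cross-validation, and key driver analysis with
#' the LCC genes as the target module.
#'
#' @param config A \code{\link{syntheticConfig}} describing the study, or a
#'   pre-built study list from \code{\link{generateSyntheticStudy}}.
#' @param outdir Optional directory; when given, every intermediate
#'   artifact is written (TSV/CSV/GMT/JSON) together with a reproducibility
#'   manifest of parameters and file checksums.
#' @param alpha_deg Adjusted-p cutoff for DEGs (default 0.01).
#' @param hub_fraction Top-centrality fraction for hubs (default 0.10).
#' @param k_range Cluster numbers searched (default 2:5).
#' @param gap_B Gap-statistic reference draws.
#' @param ssgsea_alpha ssGSEA rank-weight exponent.
#' @param kda_H,kda_alpha Key-driver layer depth and corrected-p cutoff.
#' @param seed Integer seed driving every stochastic stage.
#' @return List of stage results: \code{study}, \code{qc} (pre/post PCA),
#'   \code{deg_table}, \code{degs_up}, \code{network} (projection, lcc,
#'   centrality, hubs), \code{ora}, \code{scores}, \code{clustering},
#'   \code{cluster_tests}, \code{classifier} (model + cv), \code{kda}.
#' @export
runPipeline <- function(config = syntheticConfig(), outdir = NULL,
                        alpha_deg = 0.01, hub_fraction = 0.10,
                        k_range = 2:5, gap_B = 50L, ssgsea_alpha = 0.25,
                        kda_H = 3L, kda_alpha = 0.01, seed = 1L) {
  study <- if (inherits(config, "SyntheticConfig"))
    generateSyntheticStudy(config) else config

  norm <- quantileNormalize(study$expr)
  qc_pre <- pcaQC(norm, study$annotation)
  cb <- combatAdjust(norm, study$annotation)
  qc_post <- pcaQC(cb$corrected, study$annotation)

  deg_table <- runDGE(cb$corrected, study$annotation)
  degs_up <- selectDEGs(deg_table, alpha = alpha_deg, direction = "up")

  network <- analyzeDEGNetwork(degs_up, study$interactome,
                               hub_fraction = hub_fraction)

  universe <- rownames(study$expr)
  ora <- do.call(rbind, lapply(names(study$geneSets), function(nm) {
    r <- fisherORA(degs_up, study$geneSets[[nm]], universe)
    data.frame(set = nm, overlap = r$overlap, odds_ratio = r$odds_ratio,
               p = r$p, stringsAsFactors = FALSE)
  }))
  ora$adjP <- bhAdjust(ora$p)

  scores <- ssgseaMatrix(cb$corrected, study$geneSets,
                         alpha = ssgsea_alpha)
  case_ids <- study$annotation$sample_id[study$annotation$group == "case"]
  clustering <- clusterSubgroups(scores[, case_ids, drop = FALSE],
                                 k_range = k_range, B = gap_B, seed = seed)
  cluster_tests <- if (clustering$k == 2L)
    betweenClusterTests(scores[, case_ids, drop = FALSE],
                        clustering$labels, method = "t") else NULL

  model <- trainNB(scores[, case_ids, drop = FALSE], clustering$labels)
  cv <- cv10(scores[, case_ids, drop = FALSE], clustering$labels,
             seed = seed)

  kda <- if (length(network$lcc) > 0 &&
             length(intersect(network$lcc,
                              igraph::V(study$network)$name)) > 0)
    keyDriverAnalysis(study$network, network$lcc, H = kda_H,
                      alpha = kda_alpha) else NULL

  result <- list(study = study,
                 qc = list(pre = qc_pre, post = qc_post),
                 deg_table = deg_table, degs_up = degs_up,
                 network = network, ora = ora, scores = scores,
                 clustering = clustering, cluster_tests = cluster_tests,
                 classifier = list(model = model, cv = cv), kda = kda,
                 params = list(alpha_deg = alpha_deg,
                               hub_fraction = hub_fraction,
                               k_range = as.integer(k_range),
                               gap_B = as.integer(gap_B),
                               ssgsea_alpha = ssgsea_alpha,
                               kda_H = as.integer(kda_H),
                               kda_alpha = kda_alpha,
                               seed = as.integer(seed)))
  if (!is.null(outdir)) writePipelineBundle(result, outdir)
  result
}

#' Write a pipeline result bundle to disk
#'
#' Emits every stage artifact as plain text plus a manifest JSON of
#' parameters and per-file MD5 checksums; reruns with the same
#' configuration and seed reproduce the bundle byte for byte.
#'
#' @param result Output of \code{\link{runPipeline}}.
#' @param outdir Output directory (created if absent).
#' @return Named vector of written paths, invisibly.
#' @export
writePipelineBundle <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- writeSyntheticStudy(result$study, outdir)
  w <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    p
  }
  paths <- c(paths,
             deg_table = w(result$deg_table, "deg_table.csv"),
             centrality = if (!is.null(result$network$centrality))
               w(result$network$centrality, "centrality.csv"),
             ora = w(result$ora, "ora.csv"),
             kda = if (!is.null(result$kda)) w(result$kda, "kda.csv"))
  sp <- file.path(outdir, "ssgsea_scores.tsv")
  writeExpressionTSV(result$scores, sp)
  paths <- c(paths, scores = sp)
  lb <- file.path(outdir, "cluster_labels.csv")
  utils::write.csv(data.frame(sample_id = names(result$clustering$labels),
                              cluster = result$clustering$labels),
                   lb, row.names = FALSE, quote = FALSE)
  paths <- c(paths, labels = lb)
  mp <- file.path(outdir, "nb_model.json")
  writeNBModel(result$classifier$model, mp)
  paths <- c(paths, model = mp)
  hp <- file.path(outdir, "hubs.txt")
  writeLines(result$network$hubs, hp)
  paths <- c(paths, hubs = hp)

  manifest <- list(params = result$params,
                   n_degs_up = length(result$degs_up),
                   n_interactions = result$network$projection$n_edges,
                   n_isolated = result$network$projection$n_isolated,
                   lcc_size = length(result$network$lcc),
                   n_hubs = length(result$network$hubs),
                   chosen_k = result$clustering$k,
                   cv_accuracy = result$classifier$cv$mean_accuracy,
                   n_key_drivers = if (is.null(result$kda)) 0L
                                   else sum(result$kda$key_driver),
                   checksums = as.list(stats::setNames(
                     tools::md5sum(unlist(paths)),
                     basename(unlist(paths)))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, manifest = file.path(outdir, "manifest.json")))
}
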