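#' Configuration for the synthetic study generator
#'
#' Defines the statistical structure of a simulated multi-batch case/control
#' expression study: planted differentially expressed (DE) genes, two latent
#' case subgroups expressed as pathway-level mean shifts, a scale-free
#' interactome with a planted dense module over DE genes, and a directed
#' acyclic gene network with planted key-driver roots.
#'
#' Defaults mirror a merged salivary-gland microarray cohort at desk scale:
#' 30 cases vs 23 controls drawn from 4 source batches, a 26-pathway panel,
#' log2-scale additive effects with Gaussian noise.
#'
#' @param n_genes Number of genes in the universe.
#' @param n_samples_per_group Named count vector \code{c(case=, control=)}.
#' @param n_batches Number of source batches (datasets).
#' @param batch_shift_sd SD (log2 units) of the additive per-gene-per-batch
#'   shift.
#' @param n_de_genes Number of planted DE genes.
#' @param de_effect Absolute log2 fold-change planted on DE genes
#'   (case minus control); 0 gives a null configuration.
#' @param de_prop_up Proportion of DE genes planted as upregulated.
#' @param n_pathways Number of gene sets in the pathway panel.
#' @param pathway_size Length-2 integer range of set sizes (min >= 5).
#' @param n_active_pathways_per_cluster Pathways shifted in each latent
#'   case subgroup.
#' @param cluster_shift Additive log2 shift applied to active-pathway member
#'   genes in the corresponding subgroup's samples.
#' @param interactome_attachment Edges added per new node in the
#'   preferential-attachment interactome backbone.
#' @param module_size Size of the dense (clique) module planted over DE
#'   genes in the interactome; 0 disables planting.
#' @param n_planted_drivers Root driver nodes planted in the directed
#'   network.
#' @param driver_fanout Children per driver per layer.
#' @param network_size Total node count of the directed network.
#' @param noise_sd SD (log2 units) of i.i.d. Gaussian measurement noise.
#' @param seed Integer master seed; all component generators derive their
#'   streams from it, so identical configurations reproduce byte-identical
#'   outputs.
#' @return A validated list of class \code{SyntheticConfig}.
#' @export
syntheticConfig <- function(n_genes = 2000L,
                            n_samples_per_group = c(case = 30L, control = 23L),
                            n_batches = 4L,
                            batch_shift_sd = 0.3,
                            n_de_genes = 150L,
                            de_effect = 1,
                            de_prop_up = 0.5,
                            n_pathways = 26L,
                            pathway_size = c(10L, 40L),
                            n_active_pathways_per_cluster = 5L,
                            cluster_shift = 1,
                            interactome_attachment = 2L,
                            module_size = 15L,
                            n_planted_drivers = 3L,
                            driver_fanout = 5L,
                            network_size = 200L,
                            noise_sd = 0.5,
                            seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_samples_per_group = c(case = as.integer(n_samples_per_group[["case"]]),
                                      control = as.integer(n_samples_per_group[["control"]])),
              n_batches = as.integer(n_batches),
              batch_shift_sd = batch_shift_sd,
              n_de_genes = as.integer(n_de_genes),
              de_effect = de_effect,
              de_prop_up = de_prop_up,
              n_pathways = as.integer(n_pathways),
              pathway_size = as.integer(pathway_size),
              n_active_pathways_per_cluster = as.integer(n_active_pathways_per_cluster),
              cluster_shift = cluster_shift,
              interactome_attachment = as.integer(interactome_attachment),
              module_size = as.integer(module_size),
              n_planted_drivers = as.integer(n_planted_drivers),
              driver_fanout = as.integer(driver_fanout),
              network_size = as.integer(network_size),
              noise_sd = noise_sd,
              seed = as.integer(seed))
  class(cfg) <- "SyntheticConfig"
  validateSyntheticConfig(cfg)
  cfg
}

validateSyntheticConfig <- function(cfg) {
  counts <- c("n_genes", "n_batches", "n_pathways",
              "n_active_pathways_per_cluster", "interactome_attachment",
              "n_planted_drivers", "driver_fanout", "network_size")
  for (f in counts)
    if (cfg[[f]] < 1L) stop("invalid config: ", f, " must be >= 1")
  if (any(cfg$n_samples_per_group < 1L))
    stop("invalid config: sample counts must be >= 1")
  if (cfg$n_de_genes > cfg$n_genes)
    stop("invalid config: n_de_genes exceeds n_genes")
  if (cfg$de_effect < 0 || cfg$noise_sd < 0 || cfg$batch_shift_sd < 0 ||
      cfg$cluster_shift < 0)
    stop("invalid config: effect and noise magnitudes must be nonnegative")
  if (length(cfg$pathway_size) != 2L || cfg$pathway_size[1] < 5L ||
      cfg$pathway_size[2] < cfg$pathway_size[1])
    stop("invalid config: pathway_size must be a range with min >= 5")
  if (cfg$pathway_size[2] > cfg$n_genes)
    stop("invalid config: pathway_size max exceeds gene universe")
  if (2L * cfg$n_active_pathways_per_cluster > cfg$n_pathways)
    stop("invalid config: active pathways exceed panel size")
  if (cfg$de_prop_up < 0 || cfg$de_prop_up > 1)
    stop("invalid config: de_prop_up must lie in [0, 1]")
  invisible(cfg)
}

# One master seed fanned out to per-component streams, so regenerating one
# component never shifts another's random stream.
componentSeed <- function(cfg, component) {
  offset <- c(expression = 1L, genesets = 2L, interactome = 3L,
              network = 4L)[[component]]
  (abs(cfg$seed) %% 100000L) * 16L + offset
}

geneUniverse <- function(cfg) sprintf("G%05d", seq_len(cfg$n_genes))

#' Generate the pathway gene-set panel
#'
#' Samples \code{n_pathways} gene sets (sizes uniform within
#' \code{pathway_size}, genes drawn without replacement within a set) from
#' the gene universe.
#'
#' @param gene_universe Character vector of gene identifiers.
#' @param config A \code{\link{syntheticConfig}}.
#' @return A \linkS4class{GeneSetCollection}.
#' @export
generateGeneSets <- function(gene_universe, config) {
  validateSyntheticConfig(config)
  if (length(gene_universe) == 0L) stop("empty gene universe")
  if (config$pathway_size[2] > length(gene_universe))
    stop("invalid config: pathway_size max exceeds gene universe")
  set.seed(componentSeed(config, "genesets"))
  sz <- seq.int(config$pathway_size[1], config$pathway_size[2])
  sizes <- if (length(sz) == 1L) rep.int(sz, config$n_pathways)
           else sample(sz, config$n_pathways, replace = TRUE)
  sets <- lapply(sizes, function(s) sample(gene_universe, s))
  names(sets) <- sprintf("PW%02d", seq_len(config$n_pathways))
  GeneSetCollection(sets, rep("synthetic pathway", config$n_pathways))
}

# DE gene identities/signs and the latent subgroup structure; shared by
# expression, interactome and directed-network generation.
plantTruthCore <- function(cfg) {
  set.seed(componentSeed(cfg, "expression"))
  universe <- geneUniverse(cfg)
  de_idx <- sort(sample(cfg$n_genes, cfg$n_de_genes))
  n_up <- round(cfg$de_prop_up * cfg$n_de_genes)
  signs <- rep(-1L, cfg$n_de_genes)
  if (n_up > 0) signs[seq_len(n_up)] <- 1L
  de_genes <- stats::setNames(signs, universe[de_idx])
  pw <- generateGeneSets(universe, cfg)          # own stream
  set.seed(componentSeed(cfg, "expression") + 7L)
  active_idx <- sample(cfg$n_pathways, 2L * cfg$n_active_pathways_per_cluster)
  active <- list(cluster1 = names(pw)[active_idx[seq_len(cfg$n_active_pathways_per_cluster)]],
                 cluster2 = names(pw)[active_idx[-seq_len(cfg$n_active_pathways_per_cluster)]])
  list(universe = universe, de_genes = de_genes, geneSets = pw,
       active_pathways = active)
}

#' Generate a synthetic expression study
#'
#' Builds a gene-by-sample log2 expression matrix with additive structure:
#' per-gene baseline ~ N(7, 1), per-gene-per-batch shifts ~
#' N(0, \code{batch_shift_sd}), planted signed DE effects on case samples,
#' pathway-level subgroup shifts splitting the cases into two latent
#' clusters, and i.i.d. N(0, \code{noise_sd}) measurement noise.
#'
#' @param config A \code{\link{syntheticConfig}}.
#' @return List with \code{expr} (matrix), \code{annotation} (data.frame
#'   with sample_id, batch, group), and \code{truth} (manifest list: signed
#'   \code{de_genes}, \code{cluster_labels}, \code{active_pathways},
#'   \code{batch_labels}).
#' @export
generateExpression <- function(config) {
  validateSyntheticConfig(config)
  core <- plantTruthCore(config)
  n_case <- config$n_samples_per_group[["case"]]
  n_ctrl <- config$n_samples_per_group[["control"]]
  n <- n_case + n_ctrl
  sample_ids <- c(sprintf("CASE%03d", seq_len(n_case)),
                  sprintf("CTRL%03d", seq_len(n_ctrl)))
  group <- rep(c("case", "control"), c(n_case, n_ctrl))
  # round-robin batch assignment stratified by group, so every batch holds
  # both groups and >= 2 samples whenever sizes allow
  batch <- integer(n)
  batch[group == "case"] <- rep_len(seq_len(config$n_batches), n_case)
  batch[group == "control"] <- rep_len(seq_len(config$n_batches), n_ctrl)
  cluster <- rep_len(1:2, n_case)                # balanced latent subgroups

  set.seed(componentSeed(config, "expression") + 13L)
  mu <- stats::rnorm(config$n_genes, mean = 7, sd = 1)
  bshift <- matrix(stats::rnorm(config$n_genes * config$n_batches,
                                sd = config$batch_shift_sd),
                   config$n_genes, config$n_batches)
  m <- matrix(mu, config$n_genes, n) + bshift[, batch]
  de_idx <- match(names(core$de_genes), core$universe)
  m[de_idx, group == "case"] <- m[de_idx, group == "case"] +
    as.numeric(core$de_genes) * config$de_effect
  for (cl in 1:2) {
    members <- unique(unlist(lapply(core$active_pathways[[cl]],
                                    function(s) core$geneSets[[s]])))
    gi <- match(intersect(members, core$universe), core$universe)
    si <- which(group == "case")[cluster == cl]
    m[gi, si] <- m[gi, si] + config$cluster_shift
  }
  m <- m + matrix(stats::rnorm(config$n_genes * n, sd = config$noise_sd),
                  config$n_genes, n)
  dimnames(m) <- list(core$universe, sample_ids)

  annotation <- data.frame(sample_id = sample_ids,
                           batch = paste0("B", batch),
                           group = group, stringsAsFactors = FALSE)
  truth <- list(de_genes = core$de_genes,
                cluster_labels = stats::setNames(cluster,
                                                 sample_ids[group == "case"]),
                active_pathways = core$active_pathways,
                batch_labels = stats::setNames(paste0("B", batch), sample_ids))
  list(expr = m, annotation = annotation, truth = truth,
       geneSets = core$geneSets)
}

#' Generate a scale-free interactome with a planted dense module
#'
#' Backbone by preferential attachment (\code{interactome_attachment} edges
#' per new node) over the whole gene universe, with node labels randomly
#' permuted; a clique of \code{module_size} DE genes is then planted so that
#' the DE-induced subgraph contains a dense core.
#'
#' @param gene_universe Character vector of gene identifiers.
#' @param config A \code{\link{syntheticConfig}}.
#' @param de_genes Character vector of planted DE gene ids from which the
#'   module is drawn; defaults to the configuration's own planted
#'   upregulated DE genes (the module must survive the upregulated-DEG
#'   projection that the downstream network analysis uses).
#' @return List with \code{graph} (undirected simple \code{igraph}) and
#'   \code{planted_module} (character vector, possibly empty).
#' @export
generateInteractome <- function(gene_universe, config, de_genes = NULL) {
  validateSyntheticConfig(config)
  if (length(gene_universe) < 10L) stop("gene universe too small (< 10)")
  if (is.null(de_genes)) {
    de <- plantTruthCore(config)$de_genes
    de_genes <- names(de)[de > 0]
  }
  set.seed(componentSeed(config, "interactome"))
  g <- igraph::sample_pa(length(gene_universe), power = 1,
                         m = config$interactome_attachment,
                         directed = FALSE)
  igraph::V(g)$name <- sample(gene_universe)
  module <- character(0)
  if (config$module_size >= 2L) {
    module <- sort(sample(de_genes, min(config$module_size,
                                        length(de_genes))))
    idx <- match(module, igraph::V(g)$name)
    pairs <- utils::combn(idx, 2)
    g <- igraph::add_edges(g, as.vector(pairs))
  }
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  list(graph = g, planted_module = module)
}

#' Generate a directed acyclic gene network with planted driver roots
#'
#' Layered construction: each planted driver is a root that parents
#' \code{driver_fanout} target genes (layer 1); each layer-1 target parents
#' exactly one further target gene (layer 2) plus filler children, so the
#' drivers' downstream 2-layer neighborhoods contain the whole of their
#' designated target share while no internal or filler node's neighborhood
#' is target-enriched. Filler nodes form an independent random DAG wired
#' along a fixed topological order.
#'
#' @param gene_universe Character vector of gene identifiers.
#' @param config A \code{\link{syntheticConfig}}.
#' @param target_pool Genes from which the target set is taken, in order:
#'   the first \code{n_planted_drivers * driver_fanout * 2} pool genes
#'   become targets, with the leading genes filling the drivers' direct
#'   (layer-1) child slots. Defaults to the planted DE genes; the study
#'   generator passes the planted interactome module first, so the drivers
#'   directly regulate the dense disease module.
#' @return List with \code{graph} (directed acyclic simple \code{igraph}),
#'   \code{planted_drivers} and \code{target_set} (character vectors).
#' @export
generateDirectedNetwork <- function(gene_universe, config,
                                    target_pool = NULL) {
  validateSyntheticConfig(config)
  if (is.null(target_pool)) {
    de <- plantTruthCore(config)$de_genes
    target_pool <- names(de)[de > 0]
  }
  nt <- config$n_planted_drivers * config$driver_fanout * 2L
  if (nt > length(target_pool))
    stop("invalid config: target pool smaller than drivers x fanout x 2")
  set.seed(componentSeed(config, "network"))
  targets <- target_pool[seq_len(nt)]
  drivers <- sprintf("DRV%02d", seq_len(config$n_planted_drivers))
  n_fill <- config$network_size - config$n_planted_drivers - nt
  if (n_fill < 5L) stop("invalid config: network_size too small")
  fillers <- sample(setdiff(gene_universe, targets), n_fill)

  tg <- matrix(targets, nrow = config$n_planted_drivers)  # rows: per driver
  edges <- character(0)
  half <- config$driver_fanout
  for (d in seq_len(config$n_planted_drivers)) {
    l1 <- tg[d, seq_len(half)]
    l2 <- tg[d, half + seq_len(half)]
    edges <- c(edges, rbind(drivers[d], l1))     # driver -> layer 1
    edges <- c(edges, rbind(l1, l2))             # each l1 -> one l2 target
  }
  # filler DAG along a fixed order; first few are roots
  for (i in seq_along(fillers)) {
    if (i <= 3L) next
    parents <- sample(fillers[seq_len(i - 1L)],
                      min(sample(1:2, 1), i - 1L))
    edges <- c(edges, rbind(parents, fillers[i]))
  }
  # each layer-1 target also gets one filler child so internal target
  # nodes have mixed, non-enriched downstream neighborhoods
  l1_all <- as.vector(tg[, seq_len(half), drop = FALSE])
  for (v in l1_all) {
    edges <- c(edges, v, sample(fillers, 1L))
  }
  g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
                                   directed = TRUE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  if (!igraph::is_dag(g))
    stop("internal consistency error: generated network is not acyclic")
  list(graph = g, planted_drivers = drivers, target_set = sort(targets))
}

#' Generate the complete synthetic study
#'
#' Runs all component generators under the single master seed and merges
#' their ground-truth records into one manifest.
#'
#' @param config A \code{\link{syntheticConfig}}.
#' @return List with \code{expr}, \code{annotation}, \code{geneSets},
#'   \code{interactome}, \code{network} and \code{truth} (the complete
#'   manifest: de_genes, cluster_labels, active_pathways, planted_module,
#'   planted_drivers, target_set, batch_labels).
#' @export
generateSyntheticStudy <- function(config = syntheticConfig()) {
  ex <- generateExpression(config)
  de_up <- names(ex$truth$de_genes)[ex$truth$de_genes > 0]
  ia <- generateInteractome(geneUniverse(config), config, de_genes = de_up)
  dn <- generateDirectedNetwork(geneUniverse(config), config,
                                target_pool = c(ia$planted_module,
                                                setdiff(de_up, ia$planted_module)))
  truth <- c(ex$truth,
             list(planted_module = ia$planted_module,
                  planted_drivers = dn$planted_drivers,
                  target_set = dn$target_set))
  list(expr = ex$expr, annotation = ex$annotation, geneSets = ex$geneSets,
       interactome = ia$graph, network = dn$graph, truth = truth)
}

#' Write all synthetic study artifacts to a directory
#'
#' Emits the expression matrix TSV, annotation TSV, pathway GMT, undirected
#' and directed edge-list TSVs, and the truth manifest JSON.
#'
#' @param study Result of \code{\link{generateSyntheticStudy}}.
#' @param outdir Output directory (created if absent).
#' @return Named character vector of written paths, invisibly.
#' @export
writeSyntheticStudy <- function(study, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expr = file.path(outdir, "expression.tsv"),
             annotation = file.path(outdir, "annotation.tsv"),
             gmt = file.path(outdir, "pathways.gmt"),
             interactome = file.path(outdir, "interactome.tsv"),
             network = file.path(outdir, "directed_network.tsv"),
             truth = file.path(outdir, "truth.json"))
  writeExpressionTSV(study$expr, paths[["expr"]])
  writeAnnotationTSV(study$annotation, paths[["annotation"]])
  writeGMT(study$geneSets, paths[["gmt"]])
  writeEdgeListTSV(study$interactome, paths[["interactome"]])
  writeEdgeListTSV(study$network, paths[["network"]])
  truth <- study$truth
  truth$de_genes <- as.list(truth$de_genes)
  truth$cluster_labels <- as.list(truth$cluster_labels)
  truth$batch_labels <- as.list(truth$batch_labels)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
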