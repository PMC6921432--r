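smallCfg <- function(...) {
  args <- list(n_genes = 400L,
               n_samples_per_group = c(case = 12L, control = 10L),
               n_batches = 2L, n_de_genes = 60L, n_pathways = 10L,
               pathway_size = c(5L, 15L), n_active_pathways_per_cluster = 2L,
               module_size = 10L, network_size = 100L, seed = 7L)
  do.call(syntheticConfig, utils::modifyList(args, list(...)))
}

test_that("invalid configurations are rejected", {
  expect_error(syntheticConfig(n_de_genes = 50, n_genes = 40), "n_de_genes")
  expect_error(syntheticConfig(pathway_size = c(3, 10)), "pathway_size")
  expect_error(syntheticConfig(pathway_size = c(10, 5000), n_genes = 2000),
               "pathway_size")
  expect_error(syntheticConfig(n_batches = 0), "n_batches")
})

test_that("generation is deterministic under a fixed seed", {
  s1 <- generateSyntheticStudy(smallCfg())
  s2 <- generateSyntheticStudy(smallCfg())
  expect_identical(s1$expr, s2$expr)
  expect_identical(geneSets(s1$geneSets), geneSets(s2$geneSets))
  expect_identical(igraph::as_edgelist(s1$interactome),
                   igraph::as_edgelist(s2$interactome))
  expect_identical(igraph::as_edgelist(s1$network),
                   igraph::as_edgelist(s2$network))
  expect_identical(s1$truth, s2$truth)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeSyntheticStudy(s1, d1); writeSyntheticStudy(s2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("null configuration produces only noise-level group differences", {
  cfg <- smallCfg(de_effect = 0, cluster_shift = 0, batch_shift_sd = 0,
                  noise_sd = 0.02)
  ex <- generateExpression(cfg)
  case <- ex$annotation$group == "case"
  delta <- rowMeans(ex$expr[, case]) - rowMeans(ex$expr[, !case])
  expect_lt(mean(abs(delta)), 0.02)
})

test_that("planted effects appear where the manifest says", {
  cfg <- smallCfg(noise_sd = 0.05, de_effect = 2, cluster_shift = 0)
  ex <- generateExpression(cfg)
  case <- ex$annotation$group == "case"
  delta <- rowMeans(ex$expr[, case]) - rowMeans(ex$expr[, !case])
  de <- ex$truth$de_genes
  expect_true(all(abs(delta[names(de)] - 2 * de) < 0.3))
  nonde <- setdiff(rownames(ex$expr), names(de))
  expect_lt(max(abs(delta[nonde])), 0.3)
})

test_that("gene set generation honours count and size contracts", {
  cfg26 <- smallCfg(n_pathways = 26L)
  gs <- generateGeneSets(geneUniverse <- sprintf("G%05d", 1:400), cfg26)
  expect_identical(length(gs), 26L)
  cfg5 <- smallCfg(pathway_size = c(5L, 5L))
  gs5 <- generateGeneSets(geneUniverse, cfg5)
  expect_true(all(lengths(geneSets(gs5)) == 5L))
  expect_true(all(unlist(geneSets(gs5)) %in% geneUniverse))
})

test_that("interactome backbone is a simple graph, tree at attachment 1", {
  cfg <- smallCfg(interactome_attachment = 1L, module_size = 0L)
  ia <- generateInteractome(sprintf("G%05d", 1:400), cfg,
                            de_genes = sprintf("G%05d", 1:60))
  expect_true(igraph::is_simple(ia$graph))
  expect_identical(igraph::ecount(ia$graph), igraph::vcount(ia$graph) - 1)
  expect_length(ia$planted_module, 0)
})

test_that("planted clique module tops the degree ranks of the DE subgraph", {
  cfg <- smallCfg(module_size = 8L)
  de <- sprintf("G%05d", 1:60)
  ia <- generateInteractome(sprintf("G%05d", 1:400), cfg, de_genes = de)
  expect_length(ia$planted_module, 8)
  sub <- igraph::induced_subgraph(ia$graph, de)
  deg <- sort(igraph::degree(sub), decreasing = TRUE)
  expect_true(all(ia$planted_module %in% names(deg)[1:8]))
})

test_that("directed network is a DAG with root drivers covering their targets", {
  s <- generateSyntheticStudy(smallCfg())
  g <- s$network
  expect_true(igraph::is_dag(g))
  expect_s3_class(igraph::topo_sort(g), "igraph.vs")
  indeg <- igraph::degree(g, mode = "in")
  for (d in s$truth$planted_drivers) {
    expect_identical(unname(indeg[d]), 0)
    reach <- hLayerNeighborhood(g, d, 2)
    share <- intersect(reach, s$truth$target_set)
    # each driver's 2-layer neighborhood holds its full target share
    expect_identical(length(share), 2L * smallCfg()$driver_fanout)
  }
  covered <- unique(unlist(lapply(s$truth$planted_drivers, function(d)
    hLayerNeighborhood(g, d, 2))))
  expect_gte(mean(s$truth$target_set %in% covered), 0.8)
})

test_that("every manifest identifier resolves against the generated objects", {
  s <- generateSyntheticStudy(smallCfg())
  tr <- s$truth
  expect_true(all(names(tr$de_genes) %in% rownames(s$expr)))
  expect_setequal(names(tr$cluster_labels),
                  s$annotation$sample_id[s$annotation$group == "case"])
  expect_true(all(unlist(tr$active_pathways) %in% names(s$geneSets)))
  expect_true(all(tr$planted_module %in% igraph::V(s$interactome)$name))
  expect_true(all(tr$planted_drivers %in% igraph::V(s$network)$name))
  expect_true(all(tr$target_set %in% igraph::V(s$network)$name))
})

test_that("toy one-driver network is exactly recovered by KDA at H = 1", {
  cfg <- smallCfg(n_planted_drivers = 1L, driver_fanout = 5L,
                  network_size = 60L)
  dn <- generateDirectedNetwork(sprintf("G%05d", 1:400), cfg,
                                target_pool = sprintf("G%05d", 1:60))
  kids <- hLayerNeighborhood(dn$graph, dn$planted_drivers, 1)
  kd <- keyDriverAnalysis(dn$graph, kids, H = 1, alpha = 0.01)
  expect_identical(kd$gene[kd$key_driver], dn$planted_drivers)
  expect_identical(kd$scope[kd$key_driver], "global")
})
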