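test_that("STRING-dialect edges load with threshold and deduplication", {
  path <- withr::local_tempfile(lines = c(
    "protein1\tprotein2\tcombined_score",
    "a\tb\t500", "b\ta\t700", "c\td\t400", "d\te\t399", "e\te\t950"))
  g <- load_string_edges(path, min_score = 400)
  expect_setequal(igraph::V(g)$name, c("a", "b", "c", "d"))
  expect_equal(igraph::ecount(g), 2)          # a-b merged, d-e dropped
  ab <- igraph::E(g)[igraph::V(g)["a"] %--% igraph::V(g)["b"]]
  expect_equal(ab$score, 700)                 # max of duplicate scores
  bad <- withr::local_tempfile(lines = c(
    "protein1\tprotein2\tcombined_score", "a\tb\t1500"))
  expect_error(load_string_edges(bad), "line")
})

test_that("the generator PPI round-trips through the score filter", {
  cfg <- small_config(seed = 23)
  expr <- generate_expression(cfg)
  met <- generate_metabolites(cfg)
  kg <- generate_knowledge_graph(cfg, expr$truth, met$truth)
  dir <- withr::local_tempdir()
  write_fixture_bundle(expr, met, kg, dir)
  g <- load_string_edges(file.path(dir, "ppi.tsv"), min_score = 400)
  keep <- kg$ppi[kg$ppi$combined_score >= 400, ]
  expect_equal(igraph::ecount(g), nrow(keep))
  key_file <- paste(pmin(keep$protein1, keep$protein2),
                    pmax(keep$protein1, keep$protein2))
  el <- igraph::as_edgelist(g)
  key_graph <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  expect_setequal(key_graph, key_file)
})

test_that("seed subnetworks add connectors only when needed", {
  ## triangle of seeds: already connected, no connectors
  g <- toy_graph(cbind(c("s1", "s2", "s3"), c("s2", "s3", "s1")))
  res <- seed_subnetwork(g, c("s1", "s2", "s3"))
  expect_length(res$connectors, 0)
  expect_equal(igraph::vcount(res$subgraph), 3)
  ## two seeds bridged by one hub: exactly that hub is added
  g2 <- toy_graph(cbind(c("s1", "hub"), c("hub", "s2")))
  res2 <- seed_subnetwork(g2, c("s1", "s2"))
  expect_identical(res2$connectors, "hub")
  expect_equal(res2$connector_provenance$connector, "hub")
  ## unmapped seeds are reported, not fatal
  res3 <- seed_subnetwork(g2, c("s1", "s2", "ghost"))
  expect_identical(res3$unmapped, "ghost")
  expect_error(seed_subnetwork(g2, "ghost"), "no seeds")
})

test_that("connector insertion stays near the exhaustive Steiner optimum", {
  for (s in 1:5) {
    set.seed(130 + s)
    g <- igraph::sample_gnp(12, 0.3)
    igraph::V(g)$name <- paste0("v", 1:12)
    if (igraph::components(g)$no > 1) next
    seeds <- paste0("v", sample(12, 4))
    res <- seed_subnetwork(g, seeds, max_path_len = 11)
    opt <- steiner_optimum(g, seeds)
    expect_lte(length(res$connectors), max(2 * opt, 0))
    ## result is connected
    expect_equal(igraph::components(res$subgraph)$no, 1)
  }
})

test_that("the metabolite-gene layer is bipartite with flagged isolates", {
  met_gene <- data.frame(metabolite = c("m1", "m1", "m2"),
                         gene = c("g1", "g2", "g3"))
  res <- metabolite_gene_layer(met_gene, c("m1", "m3"))
  expect_setequal(res$genes, c("g1", "g2"))
  expect_true("m3" %in% res$isolated)
  expect_false("m1" %in% res$isolated)
  ## no metabolite-metabolite pairs can appear by construction
  expect_true(all(res$edges$metabolite %in% c("m1")))
  expect_true(all(res$edges$gene %in% c("g1", "g2")))
})

test_that("layer composition merges shared genes and tags layers", {
  g <- toy_graph(cbind(c("g1", "g2", "g4"), c("g2", "g3", "g5")))
  primary <- seed_subnetwork(g, c("g1", "g2", "g3"))
  met_layer <- metabolite_gene_layer(
    data.frame(metabolite = c("m1", "m2"), gene = c("g3", "g4")),
    c("m1", "m2"))
  secondary <- seed_subnetwork(g, met_layer$genes, allow_connectors = FALSE)
  comp <- compose_layers(primary, met_layer, secondary,
                         seed_genes = c("g1", "g2", "g3"),
                         seed_metabolites = c("m1", "m2"))
  nodes <- comp$nodes
  expect_equal(sum(nodes$name == "g3"), 1)          # shared node merged
  expect_setequal(unique(comp$edges$layer),
                  c("ppi_primary", "met_gene"))
  expect_equal(nodes$role[nodes$name == "m1"], "seed_metabolite")
  expect_equal(nodes$role[nodes$name == "g1"], "seed_gene")
  expect_equal(nodes$role[nodes$name == "g4"], "knowledge_gene")
  ## every metabolite node touches at least one met_gene edge
  mets <- nodes$name[nodes$role == "seed_metabolite"]
  expect_true(all(mets %in% c(comp$edges$from, comp$edges$to)))
})

test_that("walktrap separates two cliques joined by a single edge", {
  g <- igraph::make_full_graph(10) + igraph::make_full_graph(10)
  g <- igraph::add_edges(g, c(1, 11))
  igraph::V(g)$name <- paste0("n", 1:20)
  memb <- walktrap_communities(g)
  expect_equal(length(unique(memb)), 2)
  expect_equal(length(unique(memb[1:10])), 1)
  expect_equal(length(unique(memb[11:20])), 1)
  ## deterministic across repeated runs
  expect_identical(memb, walktrap_communities(g))
  ## complete graph collapses to one community
  kg <- igraph::make_full_graph(8)
  igraph::V(kg)$name <- paste0("k", 1:8)
  expect_equal(length(unique(walktrap_communities(kg))), 1)
  ## tiny graphs are one community
  tiny <- toy_graph(cbind("a", "b"))
  expect_equal(unname(walktrap_communities(tiny)), c(1L, 1L))
})

test_that("community filtering keeps only mixed-seed communities", {
  memb <- stats::setNames(c(1L, 1L, 1L, 2L, 2L, 3L),
                          c("g1", "g2", "m1", "g3", "g4", "m2"))
  res <- filter_mixed_communities(memb, seed_genes = c("g1", "g2", "g3"),
                                  seed_metabolites = c("m1", "m2"))
  expect_equal(res$mixed, 1L)                    # only community 1 has both
  expect_equal(res$tally$n_seed_genes[res$tally$community == 1], 2)
  expect_equal(res$tally$n_seed_metabolites[res$tally$community == 3], 1)
  expect_false(res$tally$mixed[res$tally$community == 2])
})

test_that("community enrichment delegates to the hypergeometric test", {
  universe <- paste0("g", 1:40)
  sets <- list(S = paste0("g", 1:8))
  memb <- stats::setNames(c(rep(1L, 7), 2L),
                          c(paste0("g", 1:6), "m1", "g30"))
  mixed <- filter_mixed_communities(memb, seed_genes = paste0("g", 1:6),
                                    seed_metabolites = "m1")
  enr <- community_enrichment(mixed, sets, universe)
  direct <- hypergeom_ora(paste0("g", 1:6), sets, universe)
  expect_equal(enr$p, direct$p)
  expect_equal(enr$community, 1L)
  expect_true(enr$significant)
})

test_that("cross-treatment overlap counts shared genes and pathways", {
  res <- cross_treatment_overlap(list(
    TT = list(seed_genes = c("a", "b"), pathways = c("P1", "P2")),
    CQA = list(seed_genes = "b", pathways = "P2"),
    TTCQA = list(seed_genes = "z", pathways = character(0))))
  tt_cqa <- res[res$treatment_a == "TT" & res$treatment_b == "CQA", ]
  expect_equal(tt_cqa$n_shared_genes, 1)
  expect_equal(tt_cqa$shared_pathways, "P2")
  tt_comb <- res[res$treatment_a == "TT" & res$treatment_b == "TTCQA", ]
  expect_equal(tt_comb$n_shared_genes, 0)
  expect_equal(tt_comb$n_shared_pathways, 0)
  expect_error(cross_treatment_overlap(list(a = 1)), "at least 2")
})
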