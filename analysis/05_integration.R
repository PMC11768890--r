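#!/usr/bin/env Rscript
# Stage 5: knowledge-based integration of the two omics layers.
#
# Per arm: DEGs seed a primary PPI subnetwork (score >= 400, connectors
# added by the minimum-network heuristic); affected metabolites (DAMs
# plus members of metabolite modules with significant eigenmetabolite
# shifts) seed a metabolite-gene layer and a secondary PPI over the
# partner genes; the three layers compose into one network on shared
# gene nodes; Walktrap communities containing both seed kinds are kept
# and enriched against the pathway collection; the arms are finally
# compared by shared seed genes and shared enriched pathways.

suppressPackageStartupMessages(library(phytointeract))

fx <- "results/fixtures"
counts <- read_feature_matrix(file.path(fx, "counts.tsv"))
design_e <- read_design(file.path(fx, "design_expr.tsv"))
abund <- read_feature_matrix(file.path(fx, "abundances.csv"), sep = ",")
design_m <- read_design(file.path(fx, "design_met.tsv"))
gene_sets <- read_gmt(file.path(fx, "pathways.gmt"))
met_gene <- utils::read.table(file.path(fx, "met_gene.tsv"),
                              header = TRUE, sep = "\t")
g_ppi <- load_string_edges(file.path(fx, "ppi.tsv"), min_score = 400)

filtered <- filter_low_counts(counts)
pw <- precision_weights(filtered, design_e$group, tmm_factors(filtered))
mfit <- moderate_variances(
  fit_treatment_model(pw$E, design_e$group, weights = pw$weights))
norm <- normalize_metabolites(abund)
dam <- dam_table(norm, design_m$group)

A_m <- soft_adjacency(norm, 12)
lab_m <- cut_modules(1 - tom_similarity(A_m), 5, mat = norm)
me_m <- eigenfeatures(norm, lab_m)
tests_m <- eigen_treatment_test(me_m$eigenfeatures, design_m$group)

dir.create("results/integration", showWarnings = FALSE, recursive = TRUE)
universe <- rownames(filtered)
per_arm <- list()
for (tr in c("TT", "CQA", "TTCQA", "CAW")) {
  de <- de_table(mfit, tr)
  seed_genes <- de$feature[de$status != "ns"]
  dam_tr <- dam$feature[dam$treatment == tr & dam$status != "ns"]
  mod_mets <- unlist(lapply(
    unique(tests_m$module[tests_m$significant &
                            tests_m$comparison == tr]),
    function(mm) names(lab_m)[lab_m == as.integer(sub("^ME", "", mm))]))
  seed_mets <- unique(c(dam_tr, mod_mets))
  cat(sprintf("%-6s %4d seed genes, %3d seed metabolites", tr,
              length(seed_genes), length(seed_mets)))
  if (length(seed_genes) < 2 || !length(seed_mets)) {
    cat(" -- skipped (insufficient seeds)\n")
    next
  }
  primary <- seed_subnetwork(g_ppi, seed_genes)
  met_layer <- metabolite_gene_layer(met_gene, seed_mets)
  partner <- intersect(met_layer$genes, igraph::V(g_ppi)$name)
  secondary <- if (length(partner) >= 2) seed_subnetwork(g_ppi, partner)
  else NULL
  comp <- compose_layers(primary, met_layer, secondary, seed_genes,
                         seed_mets)
  memb <- walktrap_communities(comp$graph)
  mixed <- filter_mixed_communities(memb, seed_genes, seed_mets)
  enr <- community_enrichment(mixed, gene_sets, universe)
  cat(sprintf(", %d connectors, %d communities (%d mixed)\n",
              length(primary$connectors) +
                length(if (is.null(secondary)) NULL
                       else secondary$connectors),
              length(unique(memb)), length(mixed$mixed)))
  utils::write.table(mixed$tally,
    file.path("results/integration", paste0(tr, "_communities.tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(enr))
    utils::write.table(enr,
      file.path("results/integration", paste0(tr, "_enrichment.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  members <- unlist(mixed$members[as.character(mixed$mixed)])
  per_arm[[tr]] <- list(
    seed_genes = intersect(members, seed_genes),
    pathways = if (!is.null(enr)) unique(enr$set[enr$significant])
    else character(0))
}

if (length(per_arm) >= 2) {
  ov <- cross_treatment_overlap(per_arm)
  utils::write.table(ov, "results/integration/cross_treatment.tsv",
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cat("\ncross-arm overlap (mixed-community seed genes / pathways):\n")
  for (i in seq_len(nrow(ov))) {
    cat(sprintf("  %s vs %s: %d shared genes, %d shared pathways\n",
                ov$treatment_a[i], ov$treatment_b[i],
                ov$n_shared_genes[i], ov$n_shared_pathways[i]))
  }
}
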