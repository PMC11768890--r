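#!/usr/bin/env Rscript
# Stage 4: weighted co-expression and co-abundance module analysis.
#
# Soft-thresholded (power 12) Pearson adjacency, topological overlap,
# average-linkage clustering with coherence-filtered module cut
# (minimum sizes 30 genes / 5 metabolites), eigenfeatures, module
# membership (kME), intramodular connectivity (kWithin), and Tukey
# eigenfeature treatment tests at FDR 0.05, followed by pathway
# over-representation of the gene modules.

suppressPackageStartupMessages(library(phytointeract))

fx <- "results/fixtures"
counts <- read_feature_matrix(file.path(fx, "counts.tsv"))
design_e <- read_design(file.path(fx, "design_expr.tsv"))
abund <- read_feature_matrix(file.path(fx, "abundances.csv"), sep = ",")
design_m <- read_design(file.path(fx, "design_met.tsv"))
gene_sets <- read_gmt(file.path(fx, "pathways.gmt"))

dir.create("results/comodules", showWarnings = FALSE, recursive = TRUE)

run_layer <- function(mat, groups, min_size, label) {
  A <- soft_adjacency(mat, 12)
  lab <- cut_modules(1 - tom_similarity(A), min_size, mat = mat)
  me <- eigenfeatures(mat, lab)
  tests <- eigen_treatment_test(me$eigenfeatures, groups)
  kme <- module_membership(mat, me$eigenfeatures)
  kwithin <- intramodular_connectivity(A, lab)
  utils::write.table(
    data.frame(feature = names(lab), module = unname(lab),
               kwithin = unname(kwithin)),
    file.path("results/comodules", paste0(label, "_modules.tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(tests,
    file.path("results/comodules", paste0(label, "_eigen_tests.tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s: %d modules (sizes %s); %d significant eigenfeature tests\n",
              label, length(unique(lab[lab > 0])),
              paste(sort(table(lab[lab > 0]), decreasing = TRUE),
                    collapse = ", "),
              sum(tests$significant)))
  for (i in which(tests$significant)) {
    cat(sprintf("  %s: %s vs Ctrl, estimate %.2f, q = %.3g\n",
                tests$module[i], tests$comparison[i], tests$estimate[i],
                tests$q[i]))
  }
  list(labels = lab, me = me, tests = tests, kme = kme)
}

filtered <- filter_low_counts(counts)
vst <- vst_counts(filtered, tmm_factors(filtered))
expr_mods <- run_layer(vst, design_e$group, 30, "expression")

norm <- normalize_metabolites(abund)
met_mods <- run_layer(norm, design_m$group, 5, "metabolite")

## pathway enrichment of the gene modules
universe <- rownames(filtered)
lab <- expr_mods$labels
for (m in sort(unique(lab[lab > 0]))) {
  enr <- hypergeom_ora(names(lab)[lab == m], gene_sets, universe)
  hits <- enr[enr$significant, ]
  cat(sprintf("expression module %d enriches %d pathway(s)%s\n", m,
              nrow(hits),
              if (nrow(hits)) paste0(": ",
                                     paste(hits$set, collapse = ", "))
              else ""))
  utils::write.table(enr, file.path("results/comodules",
                                    sprintf("expression_M%d_ora.tsv", m)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}
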