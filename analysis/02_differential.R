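#!/usr/bin/env Rscript
# Stage 2: differential expression and differential abundance.
#
# Counts: low-count filter (>= 10 in every sample), TMM normalization,
# log2-CPM with precision weights, moderated linear model with the
# vehicle control as reference, one DE table per arm at FDR 0.05.
# Metabolites: median normalization, log2, Pareto scaling, pooled
# t-tests per arm at FDR 0.05. PCA QC on both layers.

suppressPackageStartupMessages(library(phytointeract))

fx <- "results/fixtures"
counts <- read_feature_matrix(file.path(fx, "counts.tsv"))
design_e <- read_design(file.path(fx, "design_expr.tsv"))
abund <- read_feature_matrix(file.path(fx, "abundances.csv"), sep = ",")
design_m <- read_design(file.path(fx, "design_met.tsv"))

filtered <- filter_low_counts(counts)
cat(sprintf("%d of %d genes pass the count filter\n",
            nrow(filtered), nrow(counts)))
factors <- tmm_factors(filtered)
pw <- precision_weights(filtered, design_e$group, factors)
fit <- fit_treatment_model(pw$E, design_e$group, weights = pw$weights)
mfit <- moderate_variances(fit)
cat(sprintf("variance moderation: prior df %.1f, prior variance %.3f\n",
            mfit$d0, mfit$s0_2))

dir.create("results/differential", showWarnings = FALSE, recursive = TRUE)
for (tr in c("TT", "CQA", "TTCQA", "CAW")) {
  tab <- de_table(mfit, tr)
  utils::write.table(tab, file.path("results/differential",
                                    paste0("de_", tr, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%-6s %4d up / %4d down DEGs\n", tr,
              sum(tab$status == "up"), sum(tab$status == "down")))
}

norm <- normalize_metabolites(abund)
dam <- dam_table(norm, design_m$group)
utils::write.table(dam, "results/differential/dam.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
for (tr in c("TT", "CQA", "TTCQA", "CAW")) {
  d <- dam[dam$treatment == tr, ]
  cat(sprintf("%-6s %4d up / %4d down DAMs\n", tr,
              sum(d$status == "up"), sum(d$status == "down")))
}

pca <- pca_qc(pw$E)
cat(sprintf("expression PCA: PC1 %.0f%%, PC2 %.0f%% of variance\n",
            100 * pca$var_explained[1], 100 * pca$var_explained[2]))
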