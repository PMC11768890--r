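#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study data with planted ground truth.
#
# Emulates the study design: bulk RNA-seq counts for 2,000 genes over
# five arms (vehicle control, TT, CQA, TTCQA, full extract) at n = 8 per
# arm, 192 metabolite abundances at n = 10 per arm, and a knowledge
# bundle (scored PPI edge list, metabolite-gene map, pathway GMT). All
# downstream stages read the plain-text files written here.

suppressPackageStartupMessages(library(phytointeract))

out_dir <- "results/fixtures"
cfg <- synth_config(seed = 1)

expr <- generate_expression(cfg)
met <- generate_metabolites(cfg)
kg <- generate_knowledge_graph(cfg, expr$truth, met$truth)
manifest <- write_fixture_bundle(expr, met, kg, out_dir)

cat("Synthetic study data written to", out_dir, "\n")
cat(sprintf("  genes: %d x %d samples, metabolites: %d x %d samples\n",
            nrow(expr$counts), ncol(expr$counts),
            nrow(met$abundance), ncol(met$abundance)))
cat(sprintf("  PPI edges: %d, pathway sets: %d, met-gene links: %d\n",
            nrow(kg$ppi), length(kg$gene_sets), nrow(kg$met_gene)))
cat(sprintf("  planted: %d interacting genes, %d expression modules, %d metabolite modules\n",
            sum(expr$truth$class %in% c("synergistic", "antagonistic")),
            max(expr$truth$module), max(met$truth$module)))
print(manifest)
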