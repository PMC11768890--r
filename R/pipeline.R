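#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same
#' features; 1 for identical partitions, about 0 for independent ones.
#'
#' @param a,b integer or character label vectors of equal length.
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  ## degenerate case (e.g. all-singleton partitions): no co-clustering
  ## information; identical agreement counts as 1
  if (max_index == expected)
    return(as.numeric(sum_ij == max_index))
  (sum_ij - expected) / (max_index - expected)
}

#' Pipeline configuration
#'
#' Collects the synthetic-data configuration and every analysis
#' threshold used by \code{\link{run_pipeline}}. Defaults follow the
#' study design: count filter 10, FDR 0.05 everywhere, soft power 12,
#' minimum module sizes 30 (genes) and 5 (metabolites), PPI confidence
#' at least 400, 1000 proximity permutations, walk length 4.
#'
#' @param synth a \code{\link{synth_config}}.
#' @param min_count low-count filter threshold.
#' @param fdr FDR cutoff shared by all differential and module tests.
#' @param soft_power soft-thresholding exponent for both omics layers.
#' @param min_module_genes,min_module_mets minimum module sizes.
#' @param ppi_min_score PPI confidence threshold.
#' @param n_perm proximity permutations.
#' @param walktrap_steps random-walk length.
#' @param out_dir optional output directory; when NULL nothing is
#'   written.
#' @param seed global seed; per-stage seeds are derived from it.
#' @return List of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(synth = synth_config(),
                            min_count = 10, fdr = 0.05, soft_power = 12,
                            min_module_genes = 30, min_module_mets = 5,
                            ppi_min_score = 400, n_perm = 1000,
                            walktrap_steps = 4, out_dir = NULL,
                            seed = 1) {
  thr <- c(min_count = min_count, fdr = fdr, soft_power = soft_power,
           min_module_genes = min_module_genes,
           min_module_mets = min_module_mets,
           ppi_min_score = ppi_min_score, n_perm = n_perm,
           walktrap_steps = walktrap_steps)
  if (any(thr <= 0)) stop("all thresholds must be positive")
  synth$seed <- as.integer(seed)
  structure(list(synth = synth, min_count = min_count, fdr = fdr,
                 soft_power = soft_power,
                 min_module_genes = min_module_genes,
                 min_module_mets = min_module_mets,
                 ppi_min_score = ppi_min_score, n_perm = n_perm,
                 walktrap_steps = walktrap_steps, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# Differential expression stage shared by the pipeline and the
# acceptance checks: filter, TMM, precision weights, weighted moderated
# fit, one DE table per treatment arm.
.run_differential_expression <- function(counts, groups, min_count, fdr) {
  filtered <- filter_low_counts(counts, min_count)
  factors <- tmm_factors(filtered)
  pw <- precision_weights(filtered, groups, factors)
  fit <- fit_treatment_model(pw$E, groups, weights = pw$weights)
  mfit <- moderate_variances(fit)
  de <- lapply(stats::setNames(nm = levels(groups)[-1]), function(tr)
    de_table(mfit, tr, fdr))
  list(filtered = filtered, factors = factors, weights = pw, mfit = mfit,
       de = de)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Generates the synthetic transcriptome, metabolome and knowledge
#' bundle, then runs every stage in order: differential expression and
#' abundance, interaction classification, co-expression and co-abundance
#' module analysis with eigenfeature treatment tests, module pathway
#' enrichment, per-treatment knowledge-network integration with
#' random-walk communities, and the PPI proximity permutation test.
#' Ground-truth recovery metrics (interaction class accuracy, module
#' adjusted Rand index, eigenfeature-latent correlation) are included in
#' the summary. With \code{out_dir} set, per-stage tables and a
#' \code{summary.json} are written.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return Invisibly, a list with all stage results and the
#'   \code{summary} list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- list(config = config)
  write_out <- !is.null(config$out_dir)
  if (write_out && !dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  emit <- function(df, name) {
    if (write_out)
      utils::write.table(df, file.path(config$out_dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
  }

  ## stage 1: synthetic data
  expr <- generate_expression(config$synth)
  met <- generate_metabolites(config$synth)
  kg <- generate_knowledge_graph(config$synth, expr$truth, met$truth)
  out$expr <- expr; out$met <- met; out$kg <- kg

  ## stage 2: differential expression / abundance
  groups_e <- expr$design$group
  dx <- .run_differential_expression(expr$counts, groups_e,
                                     config$min_count, config$fdr)
  out$differential <- dx
  for (tr in names(dx$de)) emit(dx$de[[tr]], paste0("de_", tr, ".tsv"))

  norm_met <- normalize_metabolites(met$abundance)
  groups_m <- met$design$group
  dam <- dam_table(norm_met, groups_m, config$fdr)
  out$dam <- dam
  emit(dam, "dam.tsv")

  ## stage 3: interaction classification
  ctr <- interaction_contrast(dx$mfit)
  records <- classify_interactions(ctr, dx$de$TT, dx$de$CQA, dx$de$TTCQA,
                                   dx$mfit, config$fdr)
  isum <- interaction_summary(records)
  deg_sets <- lapply(dx$de, function(d) d$feature[d$status != "ns"])
  overlap <- deg_overlap(deg_sets)
  out$interaction <- list(contrast = ctr, records = records,
                          summary = isum, overlap = overlap)
  emit(records, "interaction_records.tsv")

  ## stage 4: co-expression modules
  vst <- vst_counts(dx$filtered, dx$factors)
  A_e <- soft_adjacency(vst, config$soft_power)
  tom_e <- tom_similarity(A_e)
  lab_e <- cut_modules(1 - tom_e, config$min_module_genes, mat = vst)
  me_e <- eigenfeatures(vst, lab_e)
  mods_e <- list(labels = lab_e, eigen = me_e,
                 kme = module_membership(vst, me_e$eigenfeatures),
                 kwithin = intramodular_connectivity(A_e, lab_e),
                 tests = if (ncol(me_e$eigenfeatures))
                   eigen_treatment_test(me_e$eigenfeatures, groups_e,
                                        config$fdr) else NULL)
  out$modules_expr <- mods_e
  emit(data.frame(feature = names(lab_e), module = unname(lab_e)),
       "modules_expr.tsv")
  if (!is.null(mods_e$tests)) emit(mods_e$tests, "module_tests_expr.tsv")

  ## stage 5: co-abundance modules
  A_m <- soft_adjacency(norm_met, config$soft_power)
  tom_m <- tom_similarity(A_m)
  lab_m <- cut_modules(1 - tom_m, config$min_module_mets, mat = norm_met)
  me_m <- eigenfeatures(norm_met, lab_m)
  mods_m <- list(labels = lab_m, eigen = me_m,
                 kwithin = intramodular_connectivity(A_m, lab_m),
                 tests = if (ncol(me_m$eigenfeatures))
                   eigen_treatment_test(me_m$eigenfeatures, groups_m,
                                        config$fdr) else NULL)
  out$modules_met <- mods_m
  emit(data.frame(feature = names(lab_m), module = unname(lab_m)),
       "modules_met.tsv")
  if (!is.null(mods_m$tests)) emit(mods_m$tests, "module_tests_met.tsv")

  ## stage 6: module pathway enrichment
  universe <- rownames(dx$filtered)
  mod_enrich <- list()
  for (m in sort(unique(lab_e[lab_e > 0]))) {
    mod_enrich[[paste0("M", m)]] <-
      hypergeom_ora(names(lab_e)[lab_e == m], kg$gene_sets, universe,
                    config$fdr)
  }
  out$module_enrichment <- mod_enrich

  ## stage 7: knowledge-network integration per treatment
  g_ppi <- ppi_graph(kg$ppi, config$ppi_min_score)
  sig_met_mods <- if (!is.null(mods_m$tests)) {
    unique(mods_m$tests$module[mods_m$tests$significant])
  } else character(0)
  integration <- list()
  for (tr in c("TT", "CQA", "TTCQA", "CAW")) {
    seed_genes <- deg_sets[[tr]]
    dam_tr <- dam[dam$treatment == tr & dam$status != "ns", "feature"]
    mod_mets <- unlist(lapply(sig_met_mods, function(mm) {
      if (any(mods_m$tests$module == mm & mods_m$tests$comparison == tr &
                mods_m$tests$significant)) {
        names(lab_m)[lab_m == as.integer(sub("^ME", "", mm))]
      } else character(0)
    }))
    seed_mets <- unique(c(dam_tr, mod_mets))
    if (length(seed_genes) < 2 || !length(seed_mets)) {
      integration[[tr]] <- list(skipped = TRUE, n_seed_genes =
                                  length(seed_genes),
                                n_seed_metabolites = length(seed_mets))
      next
    }
    primary <- seed_subnetwork(g_ppi, seed_genes)
    met_layer <- metabolite_gene_layer(kg$met_gene, seed_mets)
    secondary <- if (length(intersect(met_layer$genes,
                                      igraph::V(g_ppi)$name)) >= 2) {
      seed_subnetwork(g_ppi, met_layer$genes)
    } else NULL
    comp <- compose_layers(primary, met_layer, secondary, seed_genes,
                           seed_mets)
    memb <- walktrap_communities(comp$graph, config$walktrap_steps)
    mixed <- filter_mixed_communities(memb, seed_genes, seed_mets)
    enr <- community_enrichment(mixed, kg$gene_sets, universe,
                                q_threshold = config$fdr)
    mixed_members <- unlist(mixed$members[as.character(mixed$mixed)])
    integration[[tr]] <- list(
      skipped = FALSE, composite = comp, membership = memb, mixed = mixed,
      enrichment = enr,
      seed_genes = intersect(mixed_members, seed_genes),
      pathways = if (!is.null(enr)) unique(enr$set[enr$significant])
      else character(0))
  }
  out$integration <- integration
  active <- Filter(function(x) !isTRUE(x$skipped), integration)
  out$integration_overlap <- if (length(active) >= 2)
    cross_treatment_overlap(active) else NULL

  ## stage 8: PPI proximity of the DEG sets
  proximity <- list()
  for (tr in names(deg_sets)) {
    degs <- intersect(deg_sets[[tr]], igraph::V(g_ppi)$name)
    proximity[[tr]] <- if (length(degs) >= 2) {
      proximity_permutation_test(g_ppi, degs, n_perm = config$n_perm,
                                 seed = config$seed + 7L)
    } else NULL
  }
  out$proximity <- proximity

  ## ground-truth recovery metrics
  truth_cls <- expr$truth$class[records$feature]
  planted_int <- truth_cls %in% c("synergistic", "antagonistic")
  pred <- records$class
  expected <- ifelse(truth_cls == "synergistic", "positive",
                     ifelse(truth_cls == "antagonistic", "negative", "none"))
  class_accuracy <- if (any(planted_int))
    mean(pred[planted_int] == expected[planted_int]) else NA_real_
  false_interaction_rate <- if (any(truth_cls == "additive"))
    mean(pred[truth_cls == "additive"] != "none") else NA_real_

  truth_mod <- expr$truth$module[names(lab_e)]
  ari <- adjusted_rand_index(truth_mod, lab_e)
  in_planted <- truth_mod > 0
  ari_planted <- if (any(in_planted))
    adjusted_rand_index(truth_mod[in_planted], lab_e[in_planted])
  else NA_real_
  latent_cor <- if (ncol(me_e$eigenfeatures)) {
    vapply(seq_len(nrow(expr$truth$latent)), function(m) {
      max(abs(stats::cor(expr$truth$latent[m, colnames(vst)],
                         me_e$eigenfeatures)))
    }, numeric(1))
  } else numeric(0)

  summary <- list(
    seed = config$seed,
    n_genes_tested = nrow(dx$filtered),
    deg_counts = lapply(dx$de, function(d)
      list(up = sum(d$status == "up"), down = sum(d$status == "down"))),
    dam_counts = lapply(split(dam, dam$treatment), function(d)
      list(up = sum(d$status == "up"), down = sum(d$status == "down"))),
    interaction_classes = as.list(isum$by_class),
    n_modules_expr = length(unique(lab_e[lab_e > 0])),
    n_modules_met = length(unique(lab_m[lab_m > 0])),
    significant_module_tests_expr = if (!is.null(mods_e$tests))
      sum(mods_e$tests$significant) else 0L,
    significant_module_tests_met = if (!is.null(mods_m$tests))
      sum(mods_m$tests$significant) else 0L,
    mixed_communities = lapply(integration, function(x)
      if (isTRUE(x$skipped)) 0L else length(x$mixed$mixed)),
    proximity_p = lapply(proximity, function(x)
      if (is.null(x)) NA_real_ else x$p),
    recovery = list(class_accuracy = class_accuracy,
                    false_interaction_rate = false_interaction_rate,
                    module_ari = ari,
                    module_ari_planted = ari_planted,
                    latent_cor = latent_cor)
  )
  out$summary <- summary
  if (write_out)
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}
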