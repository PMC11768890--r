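#' Canonical treatment group levels
#'
#' The five treatment arms of the nested compound design: vehicle control,
#' the triterpene panel (TT), the caffeoylquinic-acid panel (CQA), the
#' twelve-compound combination (TTCQA), and the full water extract (CAW).
#'
#' @return Character vector of group levels, control first.
#' @export
treatment_groups <- function() c("Ctrl", "TT", "CQA", "TTCQA", "CAW")

#' Configuration for the synthetic multi-omics generator
#'
#' Bundles every knob of the planted-truth simulator: negative-binomial
#' bulk RNA-seq counts over five treatment groups, log-normal metabolite
#' abundances, correlated feature modules driven by per-sample latent
#' factors, and per-gene treatment effects with known additive /
#' synergistic / antagonistic structure.
#'
#' @param n_genes number of genes.
#' @param n_metabolites number of metabolites.
#' @param n_per_group_expr RNA-seq samples per group.
#' @param n_per_group_met metabolomics samples per group.
#' @param n_modules_expr number of planted co-expression modules.
#' @param n_modules_met number of planted co-abundance modules.
#' @param module_cor target within-module Pearson correlation (log scale),
#'   in [0, 1).
#' @param module_genes_frac fraction of genes assigned to planted modules.
#' @param met_module_frac fraction of metabolites assigned to planted
#'   modules.
#' @param baseline_logmean_range range (log2) of per-gene baseline mean
#'   counts.
#' @param nb_dispersion central negative-binomial dispersion phi in
#'   Var = mu + phi * mu^2; per-gene values are drawn from a gamma
#'   distribution around this value.
#' @param effect_size log2 fold-change magnitude of planted differential
#'   effects.
#' @param interaction_offset log2 offset s added to (synergistic) or
#'   subtracted from (antagonistic) the combination effect relative to the
#'   sum of the two parent effects.
#' @param frac_additive,frac_synergistic,frac_antagonistic,frac_null
#'   per-gene class proportions; must sum to 1.
#' @param caw_extra_frac fraction of genes receiving an extra effect in
#'   the full-extract arm only, emulating activity of compounds absent
#'   from the defined panels.
#' @param module_shift log2 magnitude of planted module-level treatment
#'   shifts applied to the latent factors (additive across arms, so module
#'   membership does not alter a gene's interaction class).
#' @param lib_size_range range of per-sample library-size factors.
#' @param met_sigma residual log2 standard deviation of metabolite
#'   abundances.
#' @param met_de_frac fraction of metabolites with planted treatment
#'   shifts.
#' @param seed integer RNG seed; fixing it makes all generator output
#'   byte-identical across runs.
#'
#' @return A validated list of class \code{"synth_config"}.
#' @export
synth_config <- function(n_genes = 2000,
                         n_metabolites = 192,
                         n_per_group_expr = 8,
                         n_per_group_met = 10,
                         n_modules_expr = 5,
                         n_modules_met = 3,
                         module_cor = 0.7,
                         module_genes_frac = 0.5,
                         met_module_frac = 0.65,
                         baseline_logmean_range = c(4, 10),
                         nb_dispersion = 0.05,
                         effect_size = 1,
                         interaction_offset = 1,
                         frac_additive = 0.10,
                         frac_synergistic = 0.06,
                         frac_antagonistic = 0.04,
                         frac_null = 0.80,
                         caw_extra_frac = 0.05,
                         module_shift = 1,
                         lib_size_range = c(0.7, 1.4),
                         met_sigma = 0.35,
                         met_de_frac = 0.15,
                         seed = 1) {
  cfg <- list(
    n_genes = n_genes, n_metabolites = n_metabolites,
    n_per_group_expr = n_per_group_expr, n_per_group_met = n_per_group_met,
    n_modules_expr = n_modules_expr, n_modules_met = n_modules_met,
    module_cor = module_cor, module_genes_frac = module_genes_frac,
    met_module_frac = met_module_frac,
    baseline_logmean_range = baseline_logmean_range,
    nb_dispersion = nb_dispersion,
    effect_size = effect_size, interaction_offset = interaction_offset,
    frac_additive = frac_additive, frac_synergistic = frac_synergistic,
    frac_antagonistic = frac_antagonistic, frac_null = frac_null,
    caw_extra_frac = caw_extra_frac, module_shift = module_shift,
    lib_size_range = lib_size_range, met_sigma = met_sigma,
    met_de_frac = met_de_frac, seed = as.integer(seed)
  )
  fr <- frac_additive + frac_synergistic + frac_antagonistic + frac_null
  if (abs(fr - 1) > 1e-9)
    stop("class proportions must sum to 1 (got ", fr, ")")
  counts <- c(n_genes, n_metabolites, n_per_group_expr, n_per_group_met,
              n_modules_expr, n_modules_met)
  if (any(counts < 1)) stop("all counts must be >= 1")
  if (nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (module_cor < 0 || module_cor >= 1) stop("module_cor must be in [0, 1)")
  if (any(lib_size_range <= 0) || diff(lib_size_range) < 0)
    stop("lib_size_range must be an increasing pair of positive factors")
  class(cfg) <- "synth_config"
  cfg
}

# Module-level treatment shift patterns, one row per planted module
# (recycled). Each pattern is additive in the contrast sense: the
# combination shift equals the sum of the two parent shifts, so module
# membership never changes a gene's planted interaction class.
.module_shift_patterns <- function(k, magnitude) {
  base <- list(
    c(TT = 1, TTCQA = 1, CAW = 1),     # TT effect carried through
    c(CAW = 1),                        # emerges only in the full extract
    c(CQA = 1, TTCQA = 1, CAW = 1),    # CQA effect carried through
    c(TT = -1, TTCQA = -1, CAW = -1),  # downregulation carried through
    c(CQA = -1, TTCQA = -1)            # CQA effect lost in the extract
  )
  out <- matrix(0, nrow = k, ncol = 4,
                dimnames = list(NULL, c("TT", "CQA", "TTCQA", "CAW")))
  for (i in seq_len(k)) {
    p <- base[[(i - 1L) %% length(base) + 1L]]
    out[i, names(p)] <- p * magnitude
  }
  out
}

# Draw per-feature treatment coefficients with known interaction classes.
# Returns a list with the class vector and a features x 4 beta matrix
# (TT, CQA, TTCQA, CAW on the log2 scale). `eligible` restricts non-null
# classes to a subset of features (module members keep class "null";
# their treatment structure comes from the latent-factor shifts instead,
# so module co-variation never inflates the variance of a gene whose
# planted interaction class must be recovered).
.draw_planted_effects <- function(n, cfg, eligible = rep(TRUE, n)) {
  classes <- rep("null", n)
  classes[eligible] <- sample(
    c("additive", "synergistic", "antagonistic", "null"),
    sum(eligible), replace = TRUE,
    prob = c(cfg$frac_additive, cfg$frac_synergistic,
             cfg$frac_antagonistic, cfg$frac_null))
  beta <- matrix(0, nrow = n, ncol = 4,
                 dimnames = list(NULL, c("TT", "CQA", "TTCQA", "CAW")))
  es <- cfg$effect_size
  s <- cfg$interaction_offset
  for (i in seq_len(n)) {
    cl <- classes[i]
    if (cl == "null") next
    pattern <- if (cl == "additive") {
      sample(c("TT", "CQA", "both"), 1, prob = c(0.4, 0.2, 0.4))
    } else {
      sample(c("TT", "CQA", "both", "neither"), 1,
             prob = c(0.35, 0.15, 0.3, 0.2))
    }
    sgn_tt <- sample(c(-1, 1), 1)
    sgn_cqa <- sample(c(-1, 1), 1)
    b_tt <- if (pattern %in% c("TT", "both")) sgn_tt * es else 0
    b_cqa <- if (pattern %in% c("CQA", "both")) sgn_cqa * es else 0
    delta <- switch(cl, additive = 0, synergistic = s, antagonistic = -s)
    beta[i, "TT"] <- b_tt
    beta[i, "CQA"] <- b_cqa
    beta[i, "TTCQA"] <- b_tt + b_cqa + delta
  }
  beta[, "CAW"] <- beta[, "TTCQA"]
  pool <- which(eligible)
  extra <- sort(sample(pool, size = min(length(pool),
                                        round(cfg$caw_extra_frac * n))))
  beta[extra, "CAW"] <- beta[extra, "CAW"] +
    sample(c(-1, 1), length(extra), replace = TRUE) * es
  list(classes = classes, beta = beta, caw_extra = extra)
}

.make_design <- function(n_per_group) {
  groups <- factor(rep(treatment_groups(), each = n_per_group),
                   levels = treatment_groups())
  data.frame(
    sample_id = paste0(groups, "_", sequence(rep(n_per_group, 5))),
    group = groups,
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic bulk RNA-seq count matrix with planted truth
#'
#' Counts are negative binomial with gene-specific dispersion around
#' \code{nb_dispersion}; the log2 mean of gene g in sample s is the gene
#' baseline plus its loading on the per-module latent factor of s plus the
#' planted treatment coefficient of the sample's group, and library-size
#' factors scale the means. Gene loadings are calibrated against the
#' expected negative-binomial log-scale noise so that within-module
#' correlations land near \code{module_cor}.
#'
#' @param config a \code{\link{synth_config}}.
#' @return A list with elements \code{counts} (integer genes x samples
#'   matrix), \code{design} (sample_id, group), and \code{truth} (planted
#'   classes, beta matrix, module labels, latent factors, loadings,
#'   dispersions).
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_genes
  design <- .make_design(config$n_per_group_expr)
  S <- nrow(design)
  gene_ids <- sprintf("G%05d", seq_len(n))

  ## planted modules: contiguous blocks over a shuffled gene order
  k <- config$n_modules_expr
  msize <- floor(n * config$module_genes_frac / k)
  labels <- integer(n)
  ord <- sample.int(n)
  for (m in seq_len(k)) {
    labels[ord[((m - 1) * msize + 1):(m * msize)]] <- m
  }

  baseline <- stats::runif(n, config$baseline_logmean_range[1],
                           config$baseline_logmean_range[2])
  phi <- config$nb_dispersion * stats::rgamma(n, shape = 10, rate = 10)

  ## loadings calibrated to the expected log2-scale NB noise sd
  sd_noise <- sqrt(1 / 2^baseline + phi) / log(2)
  r <- config$module_cor
  loading <- ifelse(labels > 0, sqrt(r / (1 - r)) * sd_noise, 0)

  effects <- .draw_planted_effects(n, config, eligible = labels == 0)
  shifts <- .module_shift_patterns(k, config$module_shift)

  latent <- matrix(stats::rnorm(k * S), nrow = k, ncol = S,
                   dimnames = list(paste0("ME", seq_len(k)),
                                   design$sample_id))
  grp <- as.character(design$group)
  for (m in seq_len(k)) {
    ## shifts act on the latent factor, so member genes experience
    ## graded effects of about loading * module_shift log2 units --
    ## only part of a shifted module crosses the DE threshold, as in
    ## real module/DEG overlap
    idx <- grp != "Ctrl"
    latent[m, idx] <- latent[m, idx] + shifts[m, grp[idx]]
  }

  beta_cols <- match(grp, colnames(effects$beta))  # NA for Ctrl
  group_effect <- matrix(0, n, S)
  not_ctrl <- !is.na(beta_cols)
  group_effect[, not_ctrl] <- effects$beta[, beta_cols[not_ctrl], drop = FALSE]

  factor_term <- matrix(0, n, S)
  in_mod <- labels > 0
  factor_term[in_mod, ] <- loading[in_mod] * latent[labels[in_mod], , drop = FALSE]

  lib <- stats::runif(S, config$lib_size_range[1], config$lib_size_range[2])
  log2mu <- baseline + factor_term + group_effect
  mu <- sweep(2^log2mu, 2, lib, `*`)
  counts <- matrix(
    stats::rnbinom(n * S, mu = as.vector(mu), size = rep(1 / phi, S)),
    nrow = n, ncol = S, dimnames = list(gene_ids, design$sample_id)
  )

  truth <- list(
    gene_ids = gene_ids,
    class = stats::setNames(effects$classes, gene_ids),
    beta = `rownames<-`(effects$beta, gene_ids),
    caw_extra = gene_ids[effects$caw_extra],
    module = stats::setNames(labels, gene_ids),
    module_shifts = shifts,
    latent = latent,
    loading = stats::setNames(loading, gene_ids),
    dispersion = stats::setNames(phi, gene_ids),
    lib_size_factor = stats::setNames(lib, design$sample_id)
  )
  list(counts = counts, design = design, truth = truth)
}

#' Generate a synthetic metabolite abundance matrix with planted truth
#'
#' Abundances are log-normal: the log2 abundance is a metabolite baseline
#' plus a loading on the per-module latent factor, the planted treatment
#' shift, and Gaussian noise of sd \code{met_sigma}. Category labels
#' (amino acid / nucleotide / other) are assigned so the first planted
#' module is amino-acid-enriched.
#'
#' @param config a \code{\link{synth_config}}.
#' @return A list with \code{abundance} (positive metabolites x samples
#'   matrix), \code{design}, \code{categories}, and \code{truth}.
#' @export
generate_metabolites <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 1L)
  m <- config$n_metabolites
  design <- .make_design(config$n_per_group_met)
  S <- nrow(design)
  met_ids <- sprintf("M%04d", seq_len(m))

  k <- config$n_modules_met
  msize <- floor(m * config$met_module_frac / k)
  labels <- integer(m)
  ord <- sample.int(m)
  for (mm in seq_len(k)) {
    labels[ord[((mm - 1) * msize + 1):(mm * msize)]] <- mm
  }

  cats <- character(m)
  pool <- c("amino acid", "nucleotide", "other")
  for (i in seq_len(m)) {
    p <- if (labels[i] == 1) c(0.8, 0.1, 0.1)
    else if (labels[i] == 2) c(0.3, 0.5, 0.2)
    else c(0.25, 0.2, 0.55)
    cats[i] <- sample(pool, 1, prob = p)
  }

  baseline <- stats::runif(m, 10, 20)
  r <- config$module_cor
  loading <- ifelse(labels > 0, sqrt(r / (1 - r)) * config$met_sigma, 0)

  shifts <- .module_shift_patterns(k, config$module_shift)
  latent <- matrix(stats::rnorm(k * S), nrow = k, ncol = S,
                   dimnames = list(paste0("MM", seq_len(k)),
                                   design$sample_id))
  grp <- as.character(design$group)
  for (mm in seq_len(k)) {
    idx <- grp != "Ctrl"
    latent[mm, idx] <- latent[mm, idx] + shifts[mm, grp[idx]]
  }

  ## per-metabolite planted shifts: reuse the gene effect machinery on a
  ## subset of metabolites
  bg <- which(labels == 0)
  de_idx <- sort(sample(bg, min(length(bg), round(config$met_de_frac * m))))
  sub_cfg <- config
  sub_cfg$frac_additive <- 0.5
  sub_cfg$frac_synergistic <- 0.3
  sub_cfg$frac_antagonistic <- 0.2
  sub_cfg$frac_null <- 0
  sub_cfg$caw_extra_frac <- 0
  eff <- .draw_planted_effects(length(de_idx), sub_cfg)
  beta <- matrix(0, m, 4, dimnames = list(met_ids, c("TT", "CQA", "TTCQA", "CAW")))
  beta[de_idx, ] <- eff$beta
  classes <- rep("null", m)
  classes[de_idx] <- eff$classes

  beta_cols <- match(grp, colnames(beta))
  group_effect <- matrix(0, m, S)
  not_ctrl <- !is.na(beta_cols)
  group_effect[, not_ctrl] <- beta[, beta_cols[not_ctrl], drop = FALSE]

  factor_term <- matrix(0, m, S)
  in_mod <- labels > 0
  factor_term[in_mod, ] <- loading[in_mod] * latent[labels[in_mod], , drop = FALSE]

  log2ab <- baseline + factor_term + group_effect +
    matrix(stats::rnorm(m * S, sd = config$met_sigma), m, S)
  abundance <- 2^log2ab
  dimnames(abundance) <- list(met_ids, design$sample_id)

  truth <- list(
    met_ids = met_ids,
    class = stats::setNames(classes, met_ids),
    beta = beta,
    module = stats::setNames(labels, met_ids),
    module_shifts = shifts,
    latent = latent,
    loading = stats::setNames(loading, met_ids)
  )
  list(abundance = abundance, design = design,
       categories = stats::setNames(cats, met_ids), truth = truth)
}

#' Generate a synthetic knowledge bundle
#'
#' Builds (i) a scale-free protein-protein interaction network by
#' preferential attachment over the gene universe, densified inside the
#' planted co-expression modules so that module structure survives a
#' confidence-score filter, (ii) one pathway gene set per planted module
#' with at least 60 percent overlap plus random decoy sets, and (iii) a
#' metabolite-to-gene bipartite map linking each planted metabolite
#' module to the genes of one expression module.
#'
#' @param config a \code{\link{synth_config}}.
#' @param expr_truth \code{truth} element of \code{\link{generate_expression}}.
#' @param met_truth \code{truth} element of \code{\link{generate_metabolites}}.
#' @return A list with \code{ppi} (protein1, protein2, combined_score;
#'   undirected, deduplicated, scores in [150, 999]), \code{met_gene}
#'   (metabolite, gene), \code{gene_sets} (named list), and
#'   \code{universe}.
#' @export
generate_knowledge_graph <- function(config, expr_truth, met_truth) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 2L)
  genes <- expr_truth$gene_ids
  n <- length(genes)

  g <- igraph::sample_pa(n, power = 1, m = 2, directed = FALSE)
  perm <- sample.int(n)  # detach hub positions from module blocks
  el <- igraph::as_edgelist(g, names = FALSE)
  ppi <- data.frame(protein1 = genes[perm[el[, 1]]],
                    protein2 = genes[perm[el[, 2]]],
                    combined_score = sample(150:999, nrow(el), replace = TRUE),
                    stringsAsFactors = FALSE)

  ## extra high-confidence edges inside each planted module and inside
  ## each co-regulated group (genes sharing a planted effect signature):
  ## the knowledge graph mirrors functional relatedness, so co-expressed
  ## and co-regulated genes sit closer in the PPI than random genes
  mod <- expr_truth$module
  groups <- lapply(sort(unique(mod[mod > 0])), function(m)
    names(mod)[mod == m])
  sig <- apply(expr_truth$beta, 1, paste, collapse = "/")
  de <- expr_truth$class != "null"
  for (s in unique(sig[de])) {
    members <- names(sig)[de & sig == s]
    if (length(members) >= 5) groups[[length(groups) + 1L]] <- members
  }
  ## treatment-level functional neighborhoods: all genes responsive to
  ## the same arm (this is what makes a DEG set network-proximal)
  for (trt in colnames(expr_truth$beta)) {
    members <- rownames(expr_truth$beta)[expr_truth$beta[, trt] != 0]
    if (length(members) >= 5) {
      groups[[length(groups) + 1L]] <- members
      groups[[length(groups) + 1L]] <- members  # double density
    }
  }
  extra <- lapply(groups, function(members) {
    n_extra <- round(1.5 * length(members))
    a <- sample(members, n_extra, replace = TRUE)
    b <- sample(members, n_extra, replace = TRUE)
    keep <- a != b
    data.frame(protein1 = a[keep], protein2 = b[keep],
               combined_score = sample(400:999, sum(keep), replace = TRUE),
               stringsAsFactors = FALSE)
  })
  ppi <- rbind(ppi, do.call(rbind, extra))

  ## canonical undirected key; keep the max score per pair, drop loops
  ppi <- ppi[ppi$protein1 != ppi$protein2, ]
  key <- ifelse(ppi$protein1 < ppi$protein2,
                paste(ppi$protein1, ppi$protein2),
                paste(ppi$protein2, ppi$protein1))
  o <- order(key, -ppi$combined_score)
  ppi <- ppi[o, ][!duplicated(key[o]), ]
  rownames(ppi) <- NULL

  ## pathway sets: one per planted expression module (>= 60% overlap),
  ## plus decoys
  gene_sets <- list()
  for (m in sort(unique(mod[mod > 0]))) {
    members <- names(mod)[mod == m]
    frac <- stats::runif(1, 0.6, 0.8)
    n_in <- ceiling(frac * length(members))
    set <- c(sample(members, n_in),
             sample(setdiff(genes, members), length(members) - n_in))
    gene_sets[[paste0("PW_MOD", m)]] <- sort(set)
  }
  for (d in seq_len(10)) {
    gene_sets[[sprintf("PW_RAND%02d", d)]] <- sort(sample(genes, 30))
  }

  ## metabolite-gene bipartite layer: planted metabolite module k maps to
  ## expression module k (cycled); background metabolites get random
  ## partners
  met_mod <- met_truth$module
  k_expr <- max(mod)
  rows <- list()
  for (i in seq_along(met_mod)) {
    mm <- met_mod[i]
    partners <- if (mm > 0) {
      tgt <- (mm - 1L) %% k_expr + 1L
      sample(names(mod)[mod == tgt], sample(1:3, 1))
    } else {
      sample(genes, sample(0:2, 1))
    }
    if (length(partners))
      rows[[length(rows) + 1L]] <- data.frame(
        metabolite = names(met_mod)[i], gene = partners,
        stringsAsFactors = FALSE)
  }
  met_gene <- do.call(rbind, rows)
  rownames(met_gene) <- NULL

  list(ppi = ppi, met_gene = met_gene, gene_sets = gene_sets,
       universe = genes)
}
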