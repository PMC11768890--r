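#' Write a pathway collection in GMT format
#'
#' Standard GMT: one set per line, name TAB description TAB members.
#'
#' @param gene_sets named list of character vectors.
#' @param path output file.
#' @export
write_gmt <- function(gene_sets, path) {
  stopifnot(length(names(gene_sets)) == length(gene_sets))
  lines <- vapply(names(gene_sets), function(nm) {
    paste(c(nm, "na", gene_sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a pathway collection from GMT format
#'
#' @param path GMT file.
#' @return Named list of character vectors (the description column is
#'   discarded).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("malformed GMT line: ", substr(l, 1, 50))
    parts[-(1:2)]
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  out
}

#' Read a feature-by-sample matrix written by the fixture bundle
#'
#' @param path TSV (counts) or CSV (abundances) with feature ids in the
#'   first column and sample ids in the header.
#' @param sep field separator.
#' @return Numeric matrix with feature row names.
#' @export
read_feature_matrix <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  as.matrix(df)
}

#' Read a sample design table (sample_id, group)
#'
#' @param path TSV with columns sample_id and group.
#' @return data.frame with \code{group} as a factor levelled as
#'   \code{\link{treatment_groups}}.
#' @export
read_design <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(df)))
    stop("design table must have sample_id and group columns")
  bad <- setdiff(unique(df$group), treatment_groups())
  if (length(bad)) stop("unknown groups: ", paste(bad, collapse = ", "))
  df$group <- factor(df$group, levels = treatment_groups())
  df
}

#' Write the full synthetic fixture bundle to disk
#'
#' Emits the plain-text dialects consumed by the pipeline: counts TSV,
#' abundances CSV, per-layer design TSVs, a STRING-dialect PPI edge list
#' (protein1, protein2, combined_score), a metabolite-gene TSV, a GMT
#' pathway file, metabolite categories, and ground-truth tables.
#'
#' @param expr result of \code{\link{generate_expression}}.
#' @param met result of \code{\link{generate_metabolites}}.
#' @param kg result of \code{\link{generate_knowledge_graph}}.
#' @param out_dir output directory (created if missing).
#' @return data.frame manifest with columns \code{file} and \code{md5}.
#' @export
write_fixture_bundle <- function(expr, met, kg, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  p <- function(f) file.path(out_dir, f)
  write_mat <- function(m, path, sep) {
    df <- data.frame(feature = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  write_mat(expr$counts, p("counts.tsv"), "\t")
  write_mat(met$abundance, p("abundances.csv"), ",")
  utils::write.table(expr$design, p("design_expr.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(met$design, p("design_met.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(kg$ppi, p("ppi.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(kg$met_gene, p("met_gene.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gmt(kg$gene_sets, p("pathways.gmt"))
  utils::write.table(
    data.frame(metabolite = names(met$categories),
               category = unname(met$categories)),
    p("metabolite_categories.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(gene = expr$truth$gene_ids,
               class = unname(expr$truth$class),
               expr$truth$beta,
               module = unname(expr$truth$module)),
    p("truth_genes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(metabolite = met$truth$met_ids,
               class = unname(met$truth$class),
               met$truth$beta,
               module = unname(met$truth$module)),
    p("truth_metabolites.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  files <- c("counts.tsv", "abundances.csv", "design_expr.tsv",
             "design_met.tsv", "ppi.tsv", "met_gene.tsv", "pathways.gmt",
             "metabolite_categories.tsv", "truth_genes.tsv",
             "truth_metabolites.tsv")
  data.frame(file = files,
             md5 = unname(tools::md5sum(file.path(out_dir, files))),
             stringsAsFactors = FALSE)
}
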