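#' Interaction contrast between the combination and the sum of parents
#'
#' Tests, per gene, whether the combination effect differs from the sum
#' of the two parent-panel effects: c = beta_TTCQA - beta_TT - beta_CQA.
#' In reference coding on balanced data this equals the four-group mean
#' combination mean(TTCQA) - mean(TT) - mean(CQA) + mean(Ctrl). The
#' standard error comes from the fitted coefficient covariance and the
#' moderated t uses the moderated residual variance.
#'
#' @param mfit a \code{\link{moderate_variances}} result whose model
#'   contains TT, CQA and TTCQA coefficients.
#' @return data.frame: feature, contrast c, t, p.
#' @export
interaction_contrast <- function(mfit) {
  need <- c("TT", "CQA", "TTCQA")
  miss <- setdiff(need, mfit$coef_names)
  if (length(miss)) stop("model lacks coefficient(s): ",
                         paste(miss, collapse = ", "))
  res <- contrast_test(mfit, c(TTCQA = 1, TT = -1, CQA = -1))
  data.frame(feature = res$feature, c = res$estimate, t = res$t, p = res$p,
             stringsAsFactors = FALSE)
}

# One Fig.-2-style category per classified record, derived from the
# status transitions of the parent and combination arms.
.interaction_category <- function(class, s_tt, s_cqa, s_comb, b_tt, b_cqa,
                                  b_comb) {
  parent_up <- s_tt == "up" | s_cqa == "up"
  parent_down <- s_tt == "down" | s_cqa == "down"
  no_parent <- s_tt == "ns" & s_cqa == "ns"
  parent_sum <- b_tt + b_cqa
  if (class == "negative") {
    if (s_comb == "down" && no_parent) return("new_downregulation")
    if (s_comb == "down") return("increased_downregulation")
    if (parent_up && s_comb == "ns") return("upregulation_neutralized")
    if (parent_up && s_comb == "up" && abs(b_comb) < abs(parent_sum))
      return("upregulation_diminished")
    return("other_negative")
  }
  if (class == "positive") {
    if (s_comb == "up" && no_parent) return("new_upregulation")
    if (parent_down && s_comb == "ns") return("downregulation_neutralized")
    if (parent_down && s_comb == "down" && abs(b_comb) < abs(parent_sum))
      return("downregulation_diminished")
    if (s_comb == "up") return("increased_upregulation")
    return("other_positive")
  }
  if (s_comb == "up" || (s_comb == "ns" && parent_up)) return("additive_up")
  if (s_comb == "down" || (s_comb == "ns" && parent_down)) return("additive_down")
  "additive_other"
}

#' Classify per-gene compound interactions
#'
#' Eligibility: a gene differentially expressed (q at or below the
#' threshold) in at least one of the TT, CQA, or TTCQA arms. Over the
#' eligible genes, contrast p-values are BH-adjusted; genes with a
#' significant positive contrast are classed \code{positive} (synergistic),
#' a significant negative contrast \code{negative} (antagonistic), and the
#' rest \code{none} (additive). A Fig.-2-style category label describes
#' the status transition (e.g. a parent effect neutralized or diminished
#' in the combination, or a new effect absent from both parents).
#'
#' @param contrast \code{\link{interaction_contrast}} output.
#' @param de_tt,de_cqa,de_ttcqa \code{\link{de_table}} outputs for the
#'   three arms (same feature order).
#' @param mfit the \code{\link{moderate_variances}} result supplying the
#'   coefficients.
#' @param q_threshold FDR cutoff for the contrast (default 0.05).
#' @return data.frame of eligible genes: feature, beta_TT, beta_CQA,
#'   beta_TTCQA, status_TT, status_CQA, status_TTCQA, c, q, class,
#'   category.
#' @export
classify_interactions <- function(contrast, de_tt, de_cqa, de_ttcqa, mfit,
                                  q_threshold = 0.05) {
  stopifnot(identical(contrast$feature, de_tt$feature),
            identical(contrast$feature, de_cqa$feature),
            identical(contrast$feature, de_ttcqa$feature))
  eligible <- de_tt$status != "ns" | de_cqa$status != "ns" |
    de_ttcqa$status != "ns"
  idx <- which(eligible)
  if (!length(idx)) {
    return(data.frame(feature = character(0), beta_TT = numeric(0),
                      beta_CQA = numeric(0), beta_TTCQA = numeric(0),
                      status_TT = character(0), status_CQA = character(0),
                      status_TTCQA = character(0), c = numeric(0),
                      q = numeric(0), class = character(0),
                      category = character(0), stringsAsFactors = FALSE))
  }
  q <- stats::p.adjust(contrast$p[idx], method = "BH")
  cc <- contrast$c[idx]
  cls <- ifelse(q <= q_threshold & cc > 0, "positive",
                ifelse(q <= q_threshold & cc < 0, "negative", "none"))
  b <- mfit$coefficients[idx, , drop = FALSE]
  out <- data.frame(
    feature = contrast$feature[idx],
    beta_TT = b[, "TT"], beta_CQA = b[, "CQA"], beta_TTCQA = b[, "TTCQA"],
    status_TT = de_tt$status[idx], status_CQA = de_cqa$status[idx],
    status_TTCQA = de_ttcqa$status[idx],
    c = cc, q = q, class = cls, stringsAsFactors = FALSE, row.names = NULL)
  out$category <- vapply(seq_len(nrow(out)), function(i) {
    .interaction_category(out$class[i], out$status_TT[i], out$status_CQA[i],
                          out$status_TTCQA[i], out$beta_TT[i],
                          out$beta_CQA[i], out$beta_TTCQA[i])
  }, character(1))
  out
}

#' Cross-tabulate classified interaction records
#'
#' @param records \code{\link{classify_interactions}} output.
#' @return List with \code{by_class} (counts per class), \code{table}
#'   (counts per class x category x TTCQA status), and marginal parent
#'   effect counts per class.
#' @export
interaction_summary <- function(records) {
  classes <- c("negative", "positive", "none")
  by_class <- stats::setNames(
    vapply(classes, function(cl) sum(records$class == cl), integer(1)),
    classes)
  if (nrow(records)) {
    tab <- as.data.frame(
      table(class = records$class, category = records$category,
            status_TTCQA = records$status_TTCQA),
      stringsAsFactors = FALSE)
    tab <- tab[tab$Freq > 0, , drop = FALSE]
    rownames(tab) <- NULL
  } else {
    tab <- data.frame(class = character(0), category = character(0),
                      status_TTCQA = character(0), Freq = integer(0))
  }
  parent <- do.call(rbind, lapply(classes, function(cl) {
    r <- records[records$class == cl, , drop = FALSE]
    data.frame(class = cl,
               with_TT_effect = sum(r$status_TT != "ns"),
               with_CQA_effect = sum(r$status_CQA != "ns"),
               no_parent_effect = sum(r$status_TT == "ns" &
                                        r$status_CQA == "ns"),
               stringsAsFactors = FALSE)
  }))
  list(by_class = by_class, table = tab, parent_effects = parent,
       n_records = nrow(records))
}

#' Overlap accounting of per-treatment DEG sets
#'
#' Computes how much of the parent-panel gene activity survives in the
#' combination, what the combination adds, and what the full extract
#' restores: the fraction of parent DEGs retained in the combination,
#' combination-novel DEGs and their retention in the extract, parent
#' DEGs lost in the combination but restored in the extract, and the
#' four-way common set.
#'
#' @param de_sets named list of character vectors with elements TT, CQA,
#'   TTCQA, CAW.
#' @return List: shared_fraction = |(TT u CQA) n TTCQA| / |TT u CQA|,
#'   ttcqa_novel, novel_in_caw, tt_lost_restored_in_caw, common_all.
#' @export
deg_overlap <- function(de_sets) {
  need <- c("TT", "CQA", "TTCQA", "CAW")
  stopifnot(all(need %in% names(de_sets)))
  tt <- unique(de_sets$TT); cqa <- unique(de_sets$CQA)
  comb <- unique(de_sets$TTCQA); caw <- unique(de_sets$CAW)
  parents <- union(tt, cqa)
  shared <- intersect(parents, comb)
  novel <- setdiff(comb, parents)
  restored <- intersect(setdiff(tt, comb), caw)
  list(
    shared_fraction = if (length(parents)) length(shared) / length(parents)
    else NA_real_,
    shared = shared,
    ttcqa_novel = novel,
    novel_in_caw = intersect(novel, caw),
    tt_lost_restored_in_caw = restored,
    common_all = Reduce(intersect, list(tt, cqa, comb, caw))
  )
}
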