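#' Median-of-ratios size factors
#'
#' Per-sample scale estimates robust to composition: the median across
#' genes of the ratio between a sample's count and the gene's geometric
#' mean, computed over genes with all-positive counts, rescaled to
#' geometric mean 1.
#'
#' @param counts genes x samples count matrix.
#' @return Named positive vector of size factors, geometric mean 1.
#' @export
size_factors_median_ratio <- function(counts) {
  pos <- rowSums(counts == 0) == 0
  if (sum(pos) < 10) stop("too few all-positive genes for size factors")
  lg <- log(counts[pos, , drop = FALSE])
  ref <- rowMeans(lg)
  sf <- exp(apply(lg - ref, 2, stats::median))
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(counts))
}

#' Variance-stabilizing transform for counts
#'
#' log2 counts per million with a prior count, which flattens the
#' negative-binomial mean-variance trend well enough for correlation
#' networks. By default the per-sample scale is estimated by
#' median-of-ratios size factors, which are robust against strong
#' co-expression structure leaking into total counts; TMM or other
#' factors can be passed instead.
#'
#' @param counts filtered genes x samples count matrix.
#' @param factors optional normalization factors relative to library
#'   size; when NULL, derived from
#'   \code{\link{size_factors_median_ratio}}.
#' @param prior_count offset (default 0.5).
#' @return Real matrix.
#' @export
vst_counts <- function(counts, factors = NULL, prior_count = 0.5) {
  if (is.null(factors)) {
    sf <- size_factors_median_ratio(counts)
    lib <- colSums(counts)
    factors <- sf * exp(mean(log(lib))) / lib
  }
  logcpm(counts, factors, prior_count)
}

#' Soft-thresholded correlation adjacency
#'
#' Unsigned mode raises the absolute Pearson correlation between feature
#' profiles to the power beta: \code{a_ij = |cor(x_i, x_j)|^beta};
#' signed mode uses \code{((1 + cor) / 2)^beta}. The diagonal is 1.
#'
#' @param mat features x samples matrix (>= 4 samples).
#' @param power soft-thresholding exponent beta (default 12).
#' @param mode \code{"unsigned"} (default) or \code{"signed"}.
#' @return Symmetric adjacency matrix with entries in [0, 1].
#' @export
soft_adjacency <- function(mat, power = 12, mode = c("unsigned", "signed")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(mat), ncol(mat) >= 4, power >= 1)
  v <- apply(mat, 1, stats::var)
  if (any(v == 0))
    stop("zero-variance feature(s): ",
         paste(utils::head(rownames(mat)[v == 0], 5), collapse = ", "))
  cc <- stats::cor(t(mat))
  A <- if (mode == "unsigned") abs(cc)^power else ((1 + cc) / 2)^power
  diag(A) <- 1
  A
}

#' Scale-free fit diagnostics over candidate soft powers
#'
#' For each candidate power, computes the connectivity distribution of
#' the adjacency and regresses log10 p(k) on log10 k over connectivity
#' bins. The signed R-squared (negated when the slope is positive)
#' measures scale-free topology fit; mean connectivity is reported
#' alongside.
#'
#' @param mat features x samples matrix.
#' @param powers candidate powers (default 1:20).
#' @param n_bins connectivity bins for the regression (default 10).
#' @param mode passed to \code{\link{soft_adjacency}}.
#' @return data.frame: power, sft_r2, mean_k.
#' @export
pick_soft_threshold <- function(mat, powers = 1:20, n_bins = 10,
                                mode = "unsigned") {
  cc <- stats::cor(t(mat))
  base <- if (mode == "unsigned") abs(cc) else (1 + cc) / 2
  diag(base) <- 0
  out <- lapply(powers, function(b) {
    k <- rowSums(base^b)
    mean_k <- mean(k)
    brk <- seq(min(k), max(k), length.out = n_bins + 1)
    if (length(unique(brk)) < 3)
      return(data.frame(power = b, sft_r2 = NA_real_, mean_k = mean_k))
    bin <- cut(k, brk, include.lowest = TRUE)
    dk <- tapply(k, bin, mean)
    pk <- tapply(k, bin, length) / length(k)
    ok <- dk > 0 & pk > 0
    fit <- stats::lm(log10(pk[ok]) ~ log10(dk[ok]))
    r2 <- summary(fit)$r.squared
    slope <- stats::coef(fit)[2]
    data.frame(power = b, sft_r2 = -sign(slope) * r2, mean_k = mean_k)
  })
  do.call(rbind, out)
}

#' Topological overlap matrix
#'
#' \code{TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)} with
#' \code{l_ij = sum_u a_iu a_uj} over u distinct from i and j and
#' \code{k_i} the connectivity of i excluding itself. The diagonal is 1.
#' Computed by matrix multiplication; a triple-loop reference is kept in
#' the test suite as an independent oracle.
#'
#' @param A adjacency with unit diagonal, entries in [0, 1].
#' @return Symmetric TOM matrix in [0, 1].
#' @export
tom_similarity <- function(A) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  diag(A) <- 1
  L <- A %*% A - 2 * A          # off-diagonal: sum_{u != i,j} a_iu a_uj
  k <- rowSums(A) - 1
  kmin <- outer(k, k, pmin)
  tom <- (L + A) / (kmin + 1 - A)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(A)
  tom
}

#' Cut a TOM dissimilarity dendrogram into modules
#'
#' Average-linkage hierarchical clustering of \code{1 - TOM}, a static
#' cut at \code{cut_height} times the dendrogram height, and merging of
#' clusters below \code{min_module_size} into the unassigned label 0.
#' When the data matrix is supplied, two refinements run: (i) candidate
#' modules must be coherent -- the variance explained by their first
#' principal component has to exceed \code{coherence_factor} times the
#' Marchenko-Pastur expectation for a random cluster of the same size,
#' which removes chance aggregations of unstructured features; (ii)
#' unassigned features are rescued into the module whose eigenfeature
#' they correlate with most strongly, provided the absolute correlation
#' reaches \code{kme_rescue}. Labels are ordered by decreasing module
#' size.
#'
#' @param diss square dissimilarity matrix in [0, 1] (1 - TOM).
#' @param min_module_size smallest retained module (30 for genes, 5 for
#'   metabolites).
#' @param cut_height fraction of the maximum merge height at which to
#'   cut (default 0.99).
#' @param mat optional features x samples matrix enabling the coherence
#'   filter and the kME-based rescue step.
#' @param kme_rescue minimum absolute eigenfeature correlation for
#'   rescue (default 0.5).
#' @param coherence_factor multiple of the random-cluster first-PC
#'   variance a module must explain (default 1.5).
#' @return Integer vector of labels (0 = unassigned), named by feature.
#' @export
cut_modules <- function(diss, min_module_size, cut_height = 0.99,
                        mat = NULL, kme_rescue = 0.5,
                        coherence_factor = 1.5) {
  stopifnot(is.matrix(diss), nrow(diss) == ncol(diss))
  n <- nrow(diss)
  feats <- rownames(diss)
  if (is.null(feats)) feats <- as.character(seq_len(n))
  if (n < min_module_size)
    return(stats::setNames(integer(n), feats))
  hc <- stats::hclust(stats::as.dist(diss), method = "average")

  ## coherence filter: modules must beat the Marchenko-Pastur first-PC
  ## expectation (1 + sqrt(m/n_samples))^2 / m for a random m-cluster
  apply_filters <- function(raw) {
    sizes <- table(raw)
    keep <- as.integer(names(sizes)[sizes >= min_module_size])
    labels <- integer(n)
    for (cl in keep) labels[raw == cl] <- cl
    if (!is.null(mat) && any(labels > 0)) {
      ns <- ncol(mat)
      me0 <- eigenfeatures(mat, labels)
      for (cl in as.integer(sub("^ME", "", names(me0$var_explained)))) {
        m <- sum(labels == cl)
        null_ve <- (1 + sqrt(m / ns))^2 / m
        if (me0$var_explained[paste0("ME", cl)] < coherence_factor * null_ve)
          labels[labels == cl] <- 0L
      }
    }
    labels
  }

  ## cut at a fraction of the merge-height range (not of the maximum):
  ## soft-thresholded TOM compresses dissimilarities toward 1, and the
  ## range convention keeps whole modules below the line
  h_cut <- min(hc$height) + cut_height * diff(range(hc$height))
  labels <- apply_filters(stats::cutree(hc, h = h_cut))

  if (!is.null(mat) && any(labels > 0)) {
    me <- eigenfeatures(mat, labels)
    if (ncol(me$eigenfeatures) > 0) {
      kme <- module_membership(mat, me$eigenfeatures)
      grey <- which(labels == 0)
      if (length(grey)) {
        best <- apply(abs(kme[grey, , drop = FALSE]), 1, which.max)
        best_val <- abs(kme[cbind(grey, best)])
        rescue <- best_val >= kme_rescue
        labels[grey[rescue]] <-
          as.integer(sub("^ME", "", colnames(kme)[best[rescue]]))
      }
    }
  }

  ## relabel 1..K by decreasing size
  sizes <- sort(table(labels[labels > 0]), decreasing = TRUE)
  map <- stats::setNames(seq_along(sizes), names(sizes))
  out <- integer(n)
  pos <- labels > 0
  out[pos] <- map[as.character(labels[pos])]
  stats::setNames(out, feats)
}

#' Module eigenfeatures (first principal components)
#'
#' For each module, the first right singular vector of the per-feature
#' standardized module submatrix: one value per sample, unit norm, sign
#' aligned so it correlates positively with the module's mean
#' standardized profile.
#'
#' @param mat features x samples matrix.
#' @param labels integer module labels named or ordered as \code{mat}
#'   rows; label 0 is ignored.
#' @return List with \code{eigenfeatures} (samples x modules, columns
#'   \code{ME<label>}) and \code{var_explained} per module.
#' @export
eigenfeatures <- function(mat, labels) {
  stopifnot(nrow(mat) == length(labels))
  mods <- sort(unique(labels[labels > 0]))
  me <- matrix(NA_real_, ncol(mat), length(mods),
               dimnames = list(colnames(mat), paste0("ME", mods)))
  ve <- stats::setNames(numeric(length(mods)), paste0("ME", mods))
  for (i in seq_along(mods)) {
    sub <- mat[labels == mods[i], , drop = FALSE]
    if (nrow(sub) < 2) next
    z <- t(scale(t(sub)))
    z[!is.finite(z)] <- 0
    sv <- svd(z, nu = 0, nv = 1)
    v <- sv$v[, 1]
    if (stats::cor(v, colMeans(z)) < 0) v <- -v
    me[, i] <- v
    ve[i] <- sv$d[1]^2 / sum(sv$d^2)
  }
  list(eigenfeatures = me, var_explained = ve)
}

#' Module membership (kME)
#'
#' Pearson correlation of every feature profile with every module
#' eigenfeature.
#'
#' @param mat features x samples matrix.
#' @param me samples x modules eigenfeature matrix.
#' @return Features x modules correlation matrix.
#' @export
module_membership <- function(mat, me) {
  stopifnot(ncol(mat) == nrow(me))
  kme <- stats::cor(t(mat), me)
  dimnames(kme) <- list(rownames(mat), colnames(me))
  kme
}

#' Intramodular connectivity (kWithin)
#'
#' Sum of a feature's adjacency weights to the other members of its own
#' module; 0 for unassigned features.
#'
#' @param A adjacency matrix.
#' @param labels integer module labels per feature.
#' @return Named numeric vector.
#' @export
intramodular_connectivity <- function(A, labels) {
  stopifnot(nrow(A) == length(labels))
  kw <- numeric(length(labels))
  for (m in unique(labels[labels > 0])) {
    idx <- which(labels == m)
    sub <- A[idx, idx, drop = FALSE]
    kw[idx] <- rowSums(sub) - diag(sub)
  }
  stats::setNames(kw, rownames(A))
}

#' Treatment tests on module eigenfeatures
#'
#' One-way least-squares fit of each eigenfeature on the treatment
#' groups, Tukey honest-significant-difference tests across all group
#' pairs, extraction of the versus-control comparisons, and
#' Benjamini-Hochberg adjustment across all modules and comparisons.
#'
#' @param me samples x modules eigenfeature matrix.
#' @param groups factor of group membership per sample (first level =
#'   control), aligned with \code{me} rows.
#' @param q_threshold FDR cutoff (default 0.05).
#' @return data.frame: module, comparison, estimate, p_tukey, q,
#'   significant.
#' @export
eigen_treatment_test <- function(me, groups, q_threshold = 0.05) {
  groups <- droplevels(as.factor(groups))
  stopifnot(nrow(me) == length(groups))
  if (any(table(groups) < 2)) stop("every group needs at least 2 samples")
  ctrl <- levels(groups)[1]
  rows <- list()
  for (j in seq_len(ncol(me))) {
    fit <- stats::aov(me[, j] ~ groups)
    tk <- stats::TukeyHSD(fit)$groups
    vs_ctrl <- grepl(paste0("-", ctrl, "$"), rownames(tk)) |
      grepl(paste0("^", ctrl, "-"), rownames(tk))
    tk <- tk[vs_ctrl, , drop = FALSE]
    cmp <- rownames(tk)
    est <- tk[, "diff"]
    flip <- grepl(paste0("^", ctrl, "-"), cmp)
    est[flip] <- -est[flip]
    treatment <- sub(paste0("-", ctrl, "$"), "", cmp)
    treatment[flip] <- sub(paste0("^", ctrl, "-"), "", cmp[flip])
    rows[[j]] <- data.frame(module = colnames(me)[j], comparison = treatment,
                            estimate = unname(est),
                            p_tukey = unname(tk[, "p adj"]),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p_tukey, method = "BH")
  out$significant <- out$q <= q_threshold
  rownames(out) <- NULL
  out
}
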