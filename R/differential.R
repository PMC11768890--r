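#' Remove genes with low counts in any sample
#'
#' Keeps exactly the genes whose minimum count across all samples is at
#' least \code{min_count}; the sample set is unchanged.
#'
#' @param counts integer genes x samples matrix.
#' @param min_count minimum per-sample count (default 10).
#' @return Filtered count matrix.
#' @export
filter_low_counts <- function(counts, min_count = 10) {
  stopifnot(is.matrix(counts))
  keep <- apply(counts, 1, min) >= min_count
  if (!any(keep)) warning("no genes pass the low-count filter")
  counts[keep, , drop = FALSE]
}

# One-sample TMM factor against a reference column (canonical trimmed
# weighted mean of M-values: 30% trim on M, 5% on A, inverse
# asymptotic-variance weights).
.tmm_one <- function(obs, ref, n_obs, n_ref,
                     logratio_trim = 0.3, sum_trim = 0.05) {
  logR <- log2((obs / n_obs) / (ref / n_ref))
  absE <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  v <- (n_obs - obs) / n_obs / obs + (n_ref - ref) / n_ref / ref
  fin <- is.finite(logR) & is.finite(absE)
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * logratio_trim) + 1; hiL <- n + 1 - loL
  loS <- floor(n * sum_trim) + 1; hiS <- n + 1 - loS
  keep <- (rank(logR) >= loL & rank(logR) <= hiL) &
    (rank(absE) >= loS & rank(absE) <= hiS)
  2^(sum(logR[keep] / v[keep], na.rm = TRUE) /
       sum(1 / v[keep], na.rm = TRUE))
}

#' Trimmed mean of M-values normalization factors
#'
#' Computes per-sample scaling factors by the canonical TMM procedure:
#' M- and A-values against a reference sample over genes nonzero in both,
#' trimming 30 percent of the M tails and 5 percent of the A tails, then
#' an inverse-asymptotic-variance weighted mean of the remaining
#' M-values. Factors are rescaled to geometric mean 1. The reference is
#' the sample whose upper-quartile count fraction is closest to the mean
#' upper quartile.
#'
#' @param counts filtered genes x samples count matrix (at least 2
#'   samples).
#' @param ref_sample optional column index or name of the reference.
#' @return Named numeric vector of factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, ref_sample = NULL) {
  stopifnot(is.matrix(counts), ncol(counts) >= 2)
  lib <- colSums(counts)
  if (any(lib == 0)) stop("all-zero sample(s): ",
                          paste(colnames(counts)[lib == 0], collapse = ", "))
  if (is.null(ref_sample)) {
    f75 <- apply(counts, 2, stats::quantile, probs = 0.75) / lib
    ref_sample <- which.min(abs(f75 - mean(f75)))
  }
  if (is.character(ref_sample)) ref_sample <- match(ref_sample, colnames(counts))
  ref <- counts[, ref_sample]
  f <- vapply(seq_len(ncol(counts)), function(j) {
    .tmm_one(counts[, j], ref, lib[j], lib[ref_sample])
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

#' Log2 counts per million
#'
#' \code{log2((count + prior) / (effective library + 2 * prior) * 1e6)}
#' with effective library = raw library size times the normalization
#' factor.
#'
#' @param counts genes x samples count matrix.
#' @param factors per-sample normalization factors (default all 1).
#' @param prior_count offset avoiding log of zero (default 0.5).
#' @return Real matrix of the same dimension.
#' @export
logcpm <- function(counts, factors = NULL, prior_count = 0.5) {
  if (is.null(factors)) factors <- rep(1, ncol(counts))
  if (any(factors <= 0)) stop("factors must be positive")
  eff <- colSums(counts) * factors
  log2(sweep(sweep(counts, 2, -prior_count), 2, eff + 2 * prior_count, `/`) * 1e6)
}

.design_matrix <- function(groups) {
  groups <- droplevels(as.factor(groups))
  if (any(table(groups) < 2)) stop("every group needs at least 2 samples")
  X <- stats::model.matrix(~groups)
  colnames(X) <- c("Intercept", levels(groups)[-1])
  X
}

#' Per-feature (weighted) least-squares fit against a reference group
#'
#' Fits one linear model per feature with the first factor level (the
#' control) as reference, so each non-reference coefficient is that
#' treatment's effect relative to control on the scale of the input
#' matrix (log2 for expression). With no weights and a balanced design
#' the coefficients equal group-mean differences.
#'
#' @param mat features x samples real matrix.
#' @param groups factor of group membership per sample; the first level
#'   is the reference.
#' @param weights optional positive observation-weight matrix of the same
#'   dimension as \code{mat} (precision weights).
#' @return A \code{"treatment_fit"} list: \code{coefficients} (features x
#'   coefficients, including Intercept), \code{sigma2}, \code{df_residual},
#'   \code{stdev_unscaled}, \code{cov_unscaled} (features x p x p array),
#'   and the design description.
#' @export
fit_treatment_model <- function(mat, groups, weights = NULL) {
  stopifnot(is.matrix(mat))
  groups <- droplevels(as.factor(groups))
  X <- .design_matrix(groups)
  p <- ncol(X)
  n <- ncol(mat)
  G <- nrow(mat)
  df <- n - p
  if (df <= 0) stop("non-positive residual degrees of freedom")
  if (qr(X)$rank < p) stop("singular design matrix")

  coefs <- matrix(NA_real_, G, p, dimnames = list(rownames(mat), colnames(X)))
  sigma2 <- numeric(G)
  cov_unscaled <- array(NA_real_, c(G, p, p))

  if (is.null(weights)) {
    XtXi <- solve(crossprod(X))
    H <- X %*% XtXi  # n x p
    coefs[] <- mat %*% H
    res <- mat - coefs %*% t(X)
    sigma2 <- rowSums(res^2) / df
    for (j in seq_len(p)) cov_unscaled[, j, ] <- rep(XtXi[j, ], each = G)
  } else {
    stopifnot(dim(weights) == dim(mat), all(weights > 0))
    for (g in seq_len(G)) {
      w <- weights[g, ]
      XtW <- t(X * w)
      Ci <- solve(XtW %*% X)
      b <- drop(Ci %*% (XtW %*% mat[g, ]))
      r <- mat[g, ] - drop(X %*% b)
      coefs[g, ] <- b
      sigma2[g] <- sum(w * r^2) / df
      cov_unscaled[g, , ] <- Ci
    }
  }
  stdev_unscaled <- sqrt(t(apply(cov_unscaled, 1, diag)))
  dimnames(stdev_unscaled) <- dimnames(coefs)
  structure(list(coefficients = coefs, sigma2 = sigma2, df_residual = df,
                 stdev_unscaled = stdev_unscaled,
                 cov_unscaled = cov_unscaled,
                 coef_names = colnames(X), groups = groups,
                 weighted = !is.null(weights)),
            class = "treatment_fit")
}

# Newton solve of trigamma(y) = x, vectorized (monotone decreasing).
.trigamma_inverse <- function(x) {
  y <- 0.5 + 1 / x
  y[x > 1e7] <- 1 / sqrt(x[x > 1e7])
  y[x < 1e-6] <- 1 / x[x < 1e-6]
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (max(-dif / y) < 1e-8) break
  }
  y
}

#' Empirical-Bayes moderation of residual variances
#'
#' Shrinks per-feature residual variances toward a pooled prior estimated
#' by method of moments on the log variances (an inverse-chi-square prior
#' with df d0 and scale s0^2): the posterior variance is
#' \code{(d0 * s0^2 + d * s^2) / (d0 + d)} and moderated t statistics use
#' d + d0 degrees of freedom. With \code{d0_override = 0} the fit reduces
#' to ordinary per-feature t statistics.
#'
#' @param fit a \code{\link{fit_treatment_model}} result with at least 10
#'   features.
#' @param d0_override optional fixed prior df (0 disables moderation,
#'   \code{Inf} shrinks completely to the pooled value).
#' @return A \code{"moderated_fit"}: the fit plus \code{s0_2},
#'   \code{d0}, \code{s2_post}, \code{df_total}, and per-coefficient
#'   moderated \code{t} and \code{p}.
#' @export
moderate_variances <- function(fit, d0_override = NULL) {
  stopifnot(inherits(fit, "treatment_fit"))
  s2 <- fit$sigma2
  if (length(s2) < 10) stop("need at least 10 features to moderate variances")
  if (any(s2 <= 0)) {
    warning("zero residual variances floored at machine epsilon")
    s2[s2 <= 0] <- .Machine$double.eps
  }
  d <- fit$df_residual

  z <- log(s2)
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(d / 2)
  if (!is.null(d0_override)) {
    d0 <- d0_override
    s0_2 <- if (is.finite(d0) && d0 > 0) {
      exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else mean(s2)
  } else if (evar > 0) {
    d0 <- 2 * .trigamma_inverse(evar)
    s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    ## no excess spread beyond chi-square sampling noise: infinite
    ## prior df, pooled to the mean variance
    d0 <- Inf
    s0_2 <- mean(s2)
  }

  if (is.finite(d0) && d0 > 0) {
    s2_post <- (d0 * s0_2 + d * s2) / (d0 + d)
  } else if (is.infinite(d0)) {
    s2_post <- rep(s0_2, length(s2))
  } else {
    s2_post <- s2
  }
  df_total <- min(d + d0, 1e6)

  tt <- fit$coefficients / (fit$stdev_unscaled * sqrt(s2_post))
  pp <- 2 * stats::pt(-abs(tt), df = df_total)

  out <- fit
  out$s0_2 <- s0_2
  out$d0 <- d0
  out$s2_post <- s2_post
  out$df_total <- df_total
  out$t <- tt
  out$p <- pp
  class(out) <- c("moderated_fit", "treatment_fit")
  out
}

#' Moderated test of an arbitrary coefficient contrast
#'
#' @param mfit a \code{\link{moderate_variances}} result.
#' @param contrast numeric vector over the fit's coefficients (named or
#'   in coefficient order).
#' @return data.frame with per-feature estimate, t, p.
#' @export
contrast_test <- function(mfit, contrast) {
  stopifnot(inherits(mfit, "moderated_fit"))
  p <- length(mfit$coef_names)
  L <- numeric(p)
  if (!is.null(names(contrast))) {
    miss <- setdiff(names(contrast), mfit$coef_names)
    if (length(miss)) stop("unknown coefficients: ", paste(miss, collapse = ", "))
    L[match(names(contrast), mfit$coef_names)] <- contrast
  } else {
    stopifnot(length(contrast) == p)
    L <- contrast
  }
  est <- drop(mfit$coefficients %*% L)
  G <- nrow(mfit$coefficients)
  se_unscaled <- vapply(seq_len(G), function(g) {
    sqrt(drop(t(L) %*% mfit$cov_unscaled[g, , ] %*% L))
  }, numeric(1))
  tt <- est / (se_unscaled * sqrt(mfit$s2_post))
  pp <- 2 * stats::pt(-abs(tt), df = mfit$df_total)
  data.frame(feature = rownames(mfit$coefficients), estimate = est,
             se_unscaled = se_unscaled, t = tt, p = pp,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Precision weights from the mean-variance trend
#'
#' Fits the per-gene square-root residual standard deviation against the
#' average log2 count with lowess, then evaluates the trend at each
#' fitted log-count and returns the inverse fourth power as observation
#' weights, so high-variance (low-count) observations are down-weighted
#' in the subsequent weighted fit.
#'
#' @param counts filtered genes x samples count matrix (>= 10 genes).
#' @param groups factor of group membership per sample.
#' @param factors optional TMM factors.
#' @param prior_count log-CPM offset.
#' @param span lowess span for the trend (default 0.5).
#' @return List with \code{weights} (positive matrix, same dim as
#'   counts), \code{E} (the log-CPM matrix used), and the trend points.
#' @export
precision_weights <- function(counts, groups, factors = NULL,
                              prior_count = 0.5, span = 0.5) {
  if (nrow(counts) < 10) stop("need at least 10 genes to fit the trend")
  if (is.null(factors)) factors <- rep(1, ncol(counts))
  E <- logcpm(counts, factors, prior_count)
  fit <- fit_treatment_model(E, groups)
  eff <- colSums(counts) * factors

  sx <- rowMeans(E) + mean(log2(eff + 1)) - log2(1e6)
  sy <- sqrt(sqrt(fit$sigma2))
  lo <- stats::lowess(sx, sy, f = span)
  lofun <- stats::approxfun(lo, rule = 2)

  X <- .design_matrix(groups)
  fitted_logcpm <- fit$coefficients %*% t(X)
  fitted_count <- 1e-6 * sweep(2^fitted_logcpm, 2, eff + 1, `*`)
  w <- lofun(log2(fitted_count))^-4
  dim(w) <- dim(counts)
  dimnames(w) <- dimnames(counts)
  if (any(!is.finite(w)) || any(w <= 0))
    stop("non-finite or non-positive precision weights")
  list(weights = w, E = E, trend_x = sx, trend_y = sy, lowess = lo)
}

.status_from <- function(effect, q, q_threshold) {
  ifelse(q <= q_threshold & effect > 0, "up",
         ifelse(q <= q_threshold & effect < 0, "down", "ns"))
}

#' Differential-expression table for one treatment coefficient
#'
#' Benjamini-Hochberg adjustment over all tested features; status is
#' \code{up}/\code{down} at \code{q <= q_threshold}, otherwise \code{ns}.
#'
#' @param mfit a \code{\link{moderate_variances}} result.
#' @param coefficient coefficient name (e.g. \code{"TT"}).
#' @param q_threshold FDR cutoff (default 0.05).
#' @return data.frame: feature, logFC, t, p, q, status.
#' @export
de_table <- function(mfit, coefficient, q_threshold = 0.05) {
  stopifnot(inherits(mfit, "moderated_fit"))
  if (!coefficient %in% mfit$coef_names)
    stop("unknown coefficient: ", coefficient)
  lfc <- mfit$coefficients[, coefficient]
  p <- mfit$p[, coefficient]
  q <- stats::p.adjust(p, method = "BH")
  data.frame(feature = rownames(mfit$coefficients), logFC = lfc,
             t = mfit$t[, coefficient], p = p, q = q,
             status = .status_from(lfc, q, q_threshold),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Median normalization, log2 transform and Pareto scaling
#'
#' Each sample is divided by its median and multiplied by the grand
#' median of sample medians; values are then log2 transformed and each
#' metabolite is Pareto scaled (centred and divided by the square root of
#' its standard deviation). A constant metabolite becomes a zero row with
#' a warning.
#'
#' @param abund positive metabolites x samples matrix.
#' @return Normalized real matrix.
#' @export
normalize_metabolites <- function(abund) {
  stopifnot(is.matrix(abund), all(abund > 0))
  med <- apply(abund, 2, stats::median)
  if (any(med == 0)) stop("zero sample median")
  grand <- stats::median(med)
  x <- sweep(abund, 2, grand / med, `*`)
  x <- log2(x)
  mu <- rowMeans(x)
  sdv <- apply(x, 1, stats::sd)
  if (any(sdv == 0)) {
    warning("constant metabolite(s) set to zero after scaling: ",
            paste(rownames(x)[sdv == 0], collapse = ", "))
  }
  out <- (x - mu) / sqrt(sdv)
  out[sdv == 0, ] <- 0
  out
}

#' Differential-abundance tests per treatment versus control
#'
#' Two-sample pooled-variance t-test per metabolite for each treatment
#' against the control group, with Benjamini-Hochberg adjustment across
#' all metabolites within each treatment.
#'
#' @param norm normalized metabolites x samples matrix.
#' @param groups factor of group membership; first level is control.
#' @param q_threshold FDR cutoff (default 0.05).
#' @return data.frame: feature, treatment, effect (mean difference), t,
#'   p, q, status.
#' @export
dam_table <- function(norm, groups, q_threshold = 0.05) {
  groups <- droplevels(as.factor(groups))
  ctrl <- levels(groups)[1]
  if (any(table(groups) < 2)) stop("every group needs at least 2 samples")
  out <- list()
  for (tr in levels(groups)[-1]) {
    a <- norm[, groups == tr, drop = FALSE]
    b <- norm[, groups == ctrl, drop = FALSE]
    res <- t(apply(cbind(a, b), 1, function(x) {
      xa <- x[seq_len(ncol(a))]; xb <- x[-seq_len(ncol(a))]
      tt <- tryCatch(stats::t.test(xa, xb, var.equal = TRUE),
                     error = function(e) NULL)
      if (is.null(tt)) c(mean(xa) - mean(xb), 0, 1)
      else c(unname(tt$estimate[1] - tt$estimate[2]),
             unname(tt$statistic), tt$p.value)
    }))
    q <- stats::p.adjust(res[, 3], method = "BH")
    out[[tr]] <- data.frame(
      feature = rownames(norm), treatment = tr, effect = res[, 1],
      t = res[, 2], p = res[, 3], q = q,
      status = .status_from(res[, 1], q, q_threshold),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Principal-component QC after dropping the least variable features
#'
#' Removes the lowest decile of per-feature variance, centres, and
#' computes principal components of the samples.
#'
#' @param mat features x samples real matrix (>= 3 samples).
#' @param drop_lowest_variance_decile drop the 10 percent least-variable
#'   features first (default TRUE).
#' @return List with \code{scores} (samples x PCs),
#'   \code{var_explained} (fractions summing to 1), and \code{dropped}
#'   feature names.
#' @export
pca_qc <- function(mat, drop_lowest_variance_decile = TRUE) {
  stopifnot(is.matrix(mat), ncol(mat) >= 3)
  dropped <- character(0)
  if (drop_lowest_variance_decile) {
    v <- apply(mat, 1, stats::var)
    keep <- rank(v, ties.method = "first") > floor(nrow(mat) * 0.1)
    dropped <- rownames(mat)[!keep]
    mat <- mat[keep, , drop = FALSE]
  }
  pc <- stats::prcomp(t(mat), center = TRUE, scale. = FALSE)
  list(scores = pc$x, var_explained = pc$sdev^2 / sum(pc$sdev^2),
       dropped = dropped)
}
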