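test_that("low-count filter keeps exactly the genes above threshold", {
  counts <- rbind(g1 = c(0, 50, 50, 50), g2 = c(9, 20, 30, 40),
                  g3 = c(10, 10, 10, 10), g4 = c(50, 60, 70, 80),
                  g5 = c(12, 13, 14, 15))
  out <- filter_low_counts(counts, 10)
  expect_identical(rownames(out), c("g3", "g4", "g5"))
  expect_identical(ncol(out), ncol(counts))
  expect_warning(filter_low_counts(counts, 1000), "no genes")
})

test_that("TMM factors are 1 for identical columns and pure depth shifts", {
  set.seed(1)
  base <- matrix(rnbinom(2000 * 4, mu = 100, size = 10), 2000, 4)
  same <- base[, c(1, 1, 1, 1)]
  colnames(same) <- paste0("s", 1:4)
  expect_equal(unname(tmm_factors(same)), rep(1, 4))
  ## doubling a column changes depth, not composition: every M-value is
  ## exactly zero, so both factors are exactly 1
  depth <- cbind(s1 = base[, 1], s2 = base[, 1] * 2)
  expect_equal(unname(tmm_factors(depth)), c(1, 1))
  expect_error(tmm_factors(cbind(a = rep(0, 5), b = 1:5)), "all-zero")
})

test_that("TMM trimming absorbs a block of inflated genes", {
  ## inflating 5% of genes 10-fold in one sample inflates its library
  ## size, but trimming drops those genes, so the normalized effective
  ## library of the unaffected genes stays within 5%
  set.seed(2)
  counts <- matrix(rnbinom(2000 * 4, mu = 200, size = 20), 2000, 4,
                   dimnames = list(NULL, paste0("s", 1:4)))
  eff_rel <- function(m) {
    e <- colSums(m) * tmm_factors(m, ref_sample = 1)
    e / exp(mean(log(e)))
  }
  e0 <- eff_rel(counts)
  inflated <- counts
  inflated[1:100, 2] <- inflated[1:100, 2] * 10   # 5% of genes
  e1 <- eff_rel(inflated)
  expect_lt(abs(e1[2] / e0[2] - 1), 0.05)
})

test_that("TMM factors agree with the edgeR reference implementation", {
  skip_if_not_installed("edgeR")
  set.seed(3)
  mu <- exp(stats::rnorm(3000, 5, 1.5))
  counts <- sapply(1:6, function(i)
    rnbinom(3000, mu = mu * stats::runif(1, 0.5, 2), size = 5))
  colnames(counts) <- paste0("s", 1:6)
  counts <- counts[rowSums(counts) > 0, ]
  mine <- tmm_factors(counts)
  ref <- edgeR::calcNormFactors(counts, method = "TMM")
  expect_equal(unname(mine), unname(ref), tolerance = 1e-6)
})

test_that("log-CPM follows its formula and is depth-invariant", {
  counts <- matrix(c(0, 100, 999900, 10, 200, 999790), 3, 2,
                   dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  E <- logcpm(counts, factors = c(1, 1), prior_count = 0.5)
  expect_equal(E["a", "s1"], log2(0.5 / (1e6 + 1) * 1e6), tolerance = 1e-12)
  expect_equal(round(E["a", "s1"], 2), -1)
  ## monotone within a sample
  expect_true(all(diff(E[, "s1"]) > 0))
  ## doubling counts and depth cancels up to the prior
  E2 <- logcpm(counts * 2, factors = c(1, 1))
  expect_lt(max(abs(E2[counts >= 100] - E[counts >= 100])), 0.01)
  expect_error(logcpm(counts, factors = c(0, 1)), "positive")
})

test_that("the treatment fit equals group-mean differences when balanced", {
  toy <- toy_five_group_matrix(means = c(Ctrl = 1, TT = 3, CQA = 0.5,
                                         TTCQA = 2, CAW = 1))
  fit <- fit_treatment_model(toy$mat, toy$groups)
  gm <- sapply(levels(toy$groups), function(g)
    rowMeans(toy$mat[, toy$groups == g]))
  expect_equal(unname(fit$coefficients[, "TT"]),
               unname(gm[, "TT"] - gm[, "Ctrl"]), tolerance = 1e-12)
  expect_equal(unname(fit$coefficients[, "CAW"]),
               unname(gm[, "CAW"] - gm[, "Ctrl"]), tolerance = 1e-12)
  ## permuting the samples leaves coefficients unchanged
  perm <- sample(ncol(toy$mat))
  fit2 <- fit_treatment_model(toy$mat[, perm], toy$groups[perm])
  expect_equal(fit2$coefficients, fit$coefficients, tolerance = 1e-12)
})

test_that("weighted fit matches a brute-force normal-equations solver", {
  toy <- toy_five_group_matrix(n_feat = 3)
  set.seed(11)
  w <- matrix(stats::runif(length(toy$mat), 0.2, 3), nrow(toy$mat))
  fit <- fit_treatment_model(toy$mat, toy$groups, weights = w)
  X <- stats::model.matrix(~toy$groups)
  for (g in 1:3) {
    W <- diag(w[g, ])
    b <- solve(t(X) %*% W %*% X, t(X) %*% W %*% toy$mat[g, ])
    expect_equal(unname(fit$coefficients[g, ]), unname(drop(b)),
                 tolerance = 1e-10)
  }
})

test_that("variance moderation shrinks between feature and prior", {
  toy <- toy_five_group_matrix(n_feat = 60)
  fit <- fit_treatment_model(toy$mat, toy$groups)
  ## make one variance an outlier by scaling a residual row
  fit$sigma2[1] <- fit$sigma2[1] * 40
  m <- moderate_variances(fit)
  expect_true(m$s2_post[1] < fit$sigma2[1] && m$s2_post[1] > m$s0_2)
  expect_true(all(m$s2_post > 0))
  ## d0 = 0 disables moderation entirely
  m0 <- moderate_variances(fit, d0_override = 0)
  expect_equal(m0$s2_post, fit$sigma2)
  ## d0 = Inf collapses to the pooled value
  mi <- moderate_variances(fit, d0_override = Inf)
  expect_equal(unname(mi$s2_post), rep(mi$s0_2, length(fit$sigma2)))
})

test_that("moderation agrees with the limma reference implementation", {
  skip_if_not_installed("limma")
  toy <- toy_five_group_matrix(n_feat = 200, sd = 0.5, seed = 21)
  ## heterogeneous true variances so the prior df is finite
  toy$mat <- toy$mat * stats::runif(200, 0.5, 2)
  fit <- fit_treatment_model(toy$mat, toy$groups)
  m <- moderate_variances(fit)
  sq <- limma::squeezeVar(fit$sigma2, df = fit$df_residual)
  expect_equal(m$d0, sq$df.prior, tolerance = 1e-4)
  expect_equal(m$s0_2, sq$var.prior, tolerance = 1e-4)
  expect_equal(m$s2_post, sq$var.post, tolerance = 1e-6)
})

test_that("moderated t equals ordinary t when variances are equal", {
  toy <- toy_five_group_matrix(n_feat = 40)
  fit <- fit_treatment_model(toy$mat, toy$groups)
  fit$sigma2 <- rep(0.25, 40)
  m <- moderate_variances(fit)
  expect_equal(m$s2_post, fit$sigma2)
  tt <- fit$coefficients[, "TT"] / (fit$stdev_unscaled[, "TT"] * 0.5)
  expect_equal(unname(m$t[, "TT"]), unname(tt))
})

test_that("BH adjustment and status assignment follow the definitions", {
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  toy <- toy_five_group_matrix(n_feat = 40)
  fit <- moderate_variances(fit_treatment_model(toy$mat, toy$groups))
  tab <- de_table(fit, "TT")
  expect_true(all(tab$q >= tab$p))
  expect_true(all(tab$logFC[tab$status == "up"] > 0))
  expect_true(all(tab$q[tab$status != "ns"] <= 0.05))
  ## q is non-decreasing in p rank
  expect_true(all(diff(tab$q[order(tab$p)]) >= -1e-12))
  expect_error(de_table(fit, "nope"), "unknown coefficient")
})

test_that("no features pass at FDR 0.05 under the global null", {
  cfg <- synth_config(effect_size = 0, interaction_offset = 0,
                      module_shift = 0, caw_extra_frac = 0, seed = 31)
  expr <- generate_expression(cfg)
  filtered <- filter_low_counts(expr$counts)
  f <- tmm_factors(filtered)
  pw <- precision_weights(filtered, expr$design$group, f)
  fit <- fit_treatment_model(pw$E, expr$design$group, weights = pw$weights)
  mfit <- moderate_variances(fit)
  for (tr in c("TT", "CQA", "TTCQA", "CAW")) {
    tab <- de_table(mfit, tr)
    expect_lte(mean(tab$status != "ns"), 0.01)
  }
})

test_that("precision weights are flat when the mean-variance trend is flat", {
  ## high counts with a common dispersion: log-scale variance is nearly
  ## constant across the expression range, so the trend is flat and the
  ## weights close to constant
  set.seed(41)
  mu <- 2^stats::runif(800, 8, 12)
  counts <- sapply(1:20, function(i) rnbinom(800, mu = mu, size = 10))
  rownames(counts) <- sprintf("g%03d", 1:800)
  groups <- factor(rep(treatment_groups(), each = 4),
                   levels = treatment_groups())
  colnames(counts) <- paste0(groups, "_", sequence(rep(4, 5)))
  pw <- precision_weights(counts, groups)
  expect_true(all(pw$weights > 0 & is.finite(pw$weights)))
  expect_lt(max(pw$weights) / min(pw$weights), 1.1 / 0.9)
})

test_that("precision weights increase with expression for NB counts", {
  set.seed(42)
  mu <- 2^stats::runif(800, 4, 11)
  counts <- sapply(1:20, function(i) rnbinom(800, mu = mu, size = 20))
  rownames(counts) <- sprintf("g%03d", 1:800)
  groups <- factor(rep(treatment_groups(), each = 4),
                   levels = treatment_groups())
  colnames(counts) <- paste0(groups, "_", sequence(rep(4, 5)))
  pw <- precision_weights(counts, groups)
  wbar <- rowMeans(pw$weights)
  bins <- cut(log2(mu), 5)
  mw <- tapply(wbar, bins, mean)
  expect_true(all(diff(mw) > 0))
  expect_error(precision_weights(counts[1:5, ], groups), "at least 10")
})

test_that("metabolite normalization medians, centres and Pareto-scales", {
  set.seed(51)
  ab <- matrix(2^stats::rnorm(50 * 12, 10, 1), 50, 12,
               dimnames = list(sprintf("m%02d", 1:50), NULL))
  ab <- sweep(ab, 2, stats::runif(12, 0.5, 2), `*`)
  norm <- normalize_metabolites(ab)
  ## after median normalization all sample medians of the un-scaled
  ## log2 matrix are equal; verify via the intermediate construction
  med <- apply(ab, 2, stats::median)
  x <- log2(sweep(ab, 2, stats::median(med) / med, `*`))
  expect_equal(unname(apply(2^x, 2, stats::median)),
               rep(stats::median(med), 12))
  ## Pareto scaling: mean 0, variance equal to the post-log sd
  expect_equal(unname(rowMeans(norm)), rep(0, 50), tolerance = 1e-9)
  sdv <- apply(x, 1, stats::sd)
  expect_equal(unname(apply(norm, 1, stats::var)), unname(sdv),
               tolerance = 1e-9)
  ## a metabolite that is constant after median normalization becomes a
  ## zero row with a warning
  ## inserting each sample's median leaves the medians unchanged and
  ## yields a constant row after normalization
  ab2 <- rbind(ab, const = apply(ab, 2, stats::median))
  expect_warning(n2 <- normalize_metabolites(ab2), "constant")
  expect_equal(unname(n2["const", ]), rep(0, 12))
})

test_that("abundance t-tests reproduce a hand-computed pooled t", {
  groups <- factor(c("Ctrl", "Ctrl", "Ctrl", "TT", "TT", "TT"),
                   levels = c("Ctrl", "TT"))
  mat <- matrix(c(4, 5, 6, 1, 2, 3), 1, 6,
                dimnames = list("m1", paste0("s", 1:6)))
  tab <- dam_table(mat, groups)
  expect_equal(tab$effect, -3)
  t_hand <- -3 / (1 * sqrt(1 / 3 + 1 / 3))  # pooled sd is exactly 1
  expect_equal(tab$t, t_hand, tolerance = 1e-10)
  expect_equal(round(t_hand, 3), -3.674)
  expect_equal(tab$p, 2 * stats::pt(t_hand, df = 4), tolerance = 1e-10)
  expect_equal(round(tab$p, 3), 0.021)
  ## identical group values give a null statistic
  flat <- matrix(rep(c(1, 2, 3), 2), 1, 6,
                 dimnames = list("m1", paste0("s", 1:6)))
  tf <- dam_table(flat, groups)
  expect_equal(tf$t, 0)
  expect_equal(tf$status, "ns")
})

test_that("a planted one-unit shift is detected with n = 10 per group", {
  hits <- vapply(1:10, function(s) {
    set.seed(100 + s)
    groups <- factor(rep(c("Ctrl", "TT"), each = 10),
                     levels = c("Ctrl", "TT"))
    mat <- matrix(stats::rnorm(30 * 20, sd = 0.5), 30, 20,
                  dimnames = list(sprintf("m%02d", 1:30), NULL))
    mat[1, groups == "TT"] <- mat[1, groups == "TT"] + 1
    tab <- dam_table(mat, groups)
    tab$status[1] != "ns"
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("PCA QC drops the lowest variance decile and separates clusters", {
  set.seed(61)
  mat <- matrix(stats::rnorm(100 * 12), 100, 12,
                dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:12)))
  mat[1:50, 7:12] <- mat[1:50, 7:12] + 3   # two sample clusters
  res <- pca_qc(mat)
  expect_equal(sum(res$var_explained), 1)
  expect_length(res$dropped, 10)
  ## permuting features changes nothing but sign
  perm <- sample(100)
  res2 <- pca_qc(mat[perm, ])
  expect_equal(abs(res2$scores[, 1]), abs(res$scores[, 1]), tolerance = 1e-9)
  ## PC1 separates the two planted clusters: silhouette > 0.5
  pc1 <- res$scores[, 1]
  cl <- rep(1:2, each = 6)
  sil <- vapply(1:12, function(i) {
    own <- setdiff(which(cl == cl[i]), i)
    a <- mean(abs(pc1[i] - pc1[own]))
    b <- mean(abs(pc1[i] - pc1[cl != cl[i]]))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.5)
})
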