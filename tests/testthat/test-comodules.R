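test_that("the count transform is monotone and flattens the variance trend", {
  set.seed(71)
  counts <- matrix(c(0, 5, 50, 500, 1, 6, 60, 600), 4, 2,
                   dimnames = list(paste0("g", 1:4), c("s1", "s2")))
  v <- vst_counts(counts, factors = c(1, 1))
  expect_true(all(diff(v[, "s1"]) > 0))
  ## NB counts: per-decile variance ratio shrinks drastically after log
  mu <- 2^stats::runif(2000, 4, 11)
  raw <- sapply(1:30, function(i) rnbinom(2000, mu = mu, size = 10))
  rownames(raw) <- sprintf("g%04d", 1:2000)
  dec <- cut(rank(mu), 10)
  ratio <- function(m) {
    dv <- tapply(apply(m, 1, stats::var), dec, stats::median)
    max(dv) / min(dv)
  }
  expect_gte(ratio(raw), 10)
  expect_lte(ratio(logcpm(raw)), 2)
})

test_that("soft adjacency follows |cor|^beta with unit diagonal", {
  set.seed(72)
  f <- stats::rnorm(30)
  mat <- rbind(a = f, b = f, c = f + stats::rnorm(30, sd = 1),
               d = stats::rnorm(30))
  A <- soft_adjacency(mat, 12)
  expect_equal(unname(diag(A)), rep(1, 4))
  expect_equal(A["a", "b"], 1)                      # cor 1 at any power
  cc <- stats::cor(mat["a", ], mat["c", ])
  expect_equal(A["a", "c"], abs(cc)^12)
  expect_true(isSymmetric(A))
  expect_true(all(A >= 0 & A <= 1))
  ## an exact half correlation gives 0.5^12
  expect_equal(0.5^12, 2.44140625e-4)
  mat2 <- rbind(x = c(1, -1, 1, -1, 1, -1, 1, -1),
                y = c(1, -1, 0, 0, 1, -1, 0, 0))
  ## zero-variance feature is reported by name
  expect_error(soft_adjacency(rbind(mat, e = rep(1, 30)), 12), "e")
})

test_that("soft-threshold diagnostics behave over the power grid", {
  ## heterogeneous module sizes and graded loadings, as in real
  ## co-expression data, give an approximately scale-free topology
  set.seed(73)
  sizes <- c(200, 100, 50, 25, 12)
  S <- 40
  rows <- lapply(sizes, function(m) {
    f <- stats::rnorm(S)
    lam <- stats::runif(m, 0.4, 0.98)
    outer(lam, f) + matrix(stats::rnorm(m * S, sd = sqrt(0.4)), m, S)
  })
  mat <- rbind(do.call(rbind, rows),
               matrix(stats::rnorm(150 * S), 150, S))
  rownames(mat) <- sprintf("g%04d", seq_len(nrow(mat)))
  tab <- pick_soft_threshold(mat, powers = c(1, 2, 4, 6, 8, 12))
  expect_true(all(tab$sft_r2 >= -1 & tab$sft_r2 <= 1, na.rm = TRUE))
  expect_true(all(diff(tab$mean_k) < 0))   # strictly decreasing in power
  ## some power reaches a good scale-free fit
  expect_gte(max(tab$sft_r2, na.rm = TRUE), 0.8)
})

test_that("TOM matches hand computations and the triple-loop oracle", {
  ## two nodes, a12 = 0.5: no shared neighbours
  A2 <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  t2 <- tom_similarity(A2)
  expect_equal(t2[1, 2], 0.5 / (0.5 + 1 - 0.5))
  ## identical binary neighbourhoods with a12 = 1 give overlap 1
  A3 <- matrix(c(1, 1, 1, 1, 1, 1, 1, 1, 1), 3, 3)
  A3[1, 3] <- A3[3, 1] <- 1; A3[2, 3] <- A3[3, 2] <- 1
  expect_equal(tom_similarity(A3)[1, 2], 1)
  ## random 20-node adjacencies against the brute-force oracle
  for (s in 1:3) {
    set.seed(80 + s)
    r <- matrix(stats::runif(400), 20, 20)
    A <- (r + t(r)) / 2
    diag(A) <- 1
    expect_equal(tom_similarity(A), tom_bruteforce(A), tolerance = 1e-10)
  }
  tt <- tom_similarity(A2)
  expect_true(all(tt >= 0 & tt <= 1))
})

test_that("module cutting separates perfect blocks and rejects noise", {
  set.seed(81)
  x <- stats::rnorm(12); y <- stats::rnorm(12)
  blocks <- rbind(matrix(rep(x, 6), 6, 12, byrow = TRUE),
                  matrix(rep(y, 7), 7, 12, byrow = TRUE)) +
    matrix(stats::rnorm(13 * 12, sd = 1e-6), 13, 12)
  rownames(blocks) <- paste0("f", 1:13)
  tomd <- 1 - tom_similarity(soft_adjacency(blocks, 12))
  lab <- cut_modules(tomd, 5)
  expect_equal(length(unique(lab)), 2)
  expect_equal(length(unique(lab[1:6])), 1)
  expect_equal(length(unique(lab[7:13])), 1)
  ## structureless matrix: >= 90% unassigned
  set.seed(82)
  Z <- matrix(stats::rnorm(300 * 40), 300, 40,
              dimnames = list(paste0("g", 1:300), NULL))
  lz <- cut_modules(1 - tom_similarity(soft_adjacency(Z, 12)), 30, mat = Z)
  expect_gte(mean(lz == 0), 0.9)
  ## fewer features than the minimum size: all unassigned
  expect_true(all(cut_modules(tomd[1:3, 1:3], 5) == 0))
})

test_that("planted modules are recovered with high Rand index", {
  cfg <- synth_config(n_genes = 500, module_genes_frac = 0.5,
                      n_modules_expr = 5, effect_size = 0,
                      caw_extra_frac = 0, seed = 83)
  expr <- generate_expression(cfg)
  vst <- vst_counts(expr$counts)
  lab <- cut_modules(1 - tom_similarity(soft_adjacency(vst, 12)), 30,
                     mat = vst)
  expect_gte(adjusted_rand_index(expr$truth$module, lab), 0.8)
})

test_that("eigenfeatures are unit-norm aligned first components", {
  ## identical features: eigenfeature proportional to the profile
  prof <- stats::rnorm(10)
  mat <- rbind(a = prof, b = prof, c = prof)
  colnames(mat) <- paste0("s", 1:10)
  me <- eigenfeatures(mat, c(1, 1, 1))
  expect_equal(sum(me$eigenfeatures[, 1]^2), 1)
  expect_equal(unname(me$var_explained), 1)
  expect_gt(stats::cor(me$eigenfeatures[, 1], prof), 0.999)
  ## flipping all features flips nothing after sign alignment
  me2 <- eigenfeatures(-mat, c(1, 1, 1))
  expect_equal(stats::cor(me2$eigenfeatures[, 1], -prof), 1,
               tolerance = 1e-9)
  ## eigenfeature explains at least as much as any single feature
  set.seed(84)
  mm <- matrix(stats::rnorm(8 * 20), 8, 20)
  mm[1:4, ] <- mm[1:4, ] + rep(stats::rnorm(20, sd = 2), each = 4)
  rownames(mm) <- paste0("g", 1:8)
  me3 <- eigenfeatures(mm, rep(1, 8))
  z <- t(scale(t(mm)))
  single_best <- max(vapply(1:8, function(i)
    mean(stats::cor(z[i, ], t(z))^2), numeric(1)))
  expect_gte(me3$var_explained[1] + 1e-9, single_best)
})

test_that("module membership and intramodular connectivity are consistent", {
  set.seed(85)
  f <- stats::rnorm(16)
  mat <- rbind(a = f, b = f + stats::rnorm(16, sd = 0.3),
               c = stats::rnorm(16))
  me <- eigenfeatures(mat, c(1, 1, 0))
  kme <- module_membership(mat, me$eigenfeatures)
  expect_true(all(abs(kme) <= 1))
  expect_gt(kme["a", 1], 0.95)             # near-copy of the eigenfeature
  expect_gt(abs(kme["a", 1]), abs(kme["c", 1]))
  A <- matrix(c(1, 0.3, 0.3, 1), 2, 2, dimnames = list(c("a", "b"),
                                                       c("a", "b")))
  kw <- intramodular_connectivity(A, c(1, 1))
  expect_equal(unname(kw), c(0.3, 0.3))
  ## all-ones adjacency, module of size m: kWithin = m - 1
  m <- 5
  A1 <- matrix(1, m, m)
  expect_equal(unname(intramodular_connectivity(A1, rep(1, m))),
               rep(m - 1, m))
  expect_true(all(kw <= 2 - 1))
})

test_that("eigenfeature treatment tests find the shifted group only", {
  ## power under Tukey + BH at n = 8: a 2-sd shift gives a moderated
  ## detection rate (about 0.7 analytically); a 3-sd shift is detected
  ## almost always. Specificity stays clean in both regimes.
  groups <- factor(rep(treatment_groups(), each = 8),
                   levels = treatment_groups())
  run <- function(delta) {
    t(vapply(1:20, function(s) {
      set.seed(90 + s)
      me <- cbind(M1 = stats::rnorm(40))
      me[groups == "TT", 1] <- me[groups == "TT", 1] + delta
      res <- eigen_treatment_test(me, groups)
      c(tt = res$significant[res$comparison == "TT"],
        other = sum(res$significant[res$comparison != "TT"]))
    }, c(tt = TRUE, other = 1)))
  }
  strong <- run(3)
  expect_gte(mean(strong[, "tt"]), 0.9)
  expect_lte(mean(strong[, "other"] > 0), 0.1)
  mid <- run(2)
  expect_gte(mean(mid[, "tt"]), 0.5)
  ## identical group means: nothing significant
  set.seed(99)
  me0 <- cbind(M1 = stats::rnorm(40))
  expect_false(any(eigen_treatment_test(me0, groups)$significant))
})

test_that("Tukey reduces to the ordinary t-test with two groups", {
  set.seed(101)
  g2 <- factor(rep(c("Ctrl", "TT"), each = 6), levels = c("Ctrl", "TT"))
  me <- cbind(M1 = c(stats::rnorm(6), stats::rnorm(6, mean = 1)))
  res <- eigen_treatment_test(me, g2)
  tt <- stats::t.test(me[g2 == "TT", 1], me[g2 == "Ctrl", 1],
                      var.equal = TRUE)
  expect_equal(res$p_tukey, tt$p.value, tolerance = 1e-6)
  expect_equal(res$estimate, unname(diff(tapply(me[, 1], g2, mean))),
               tolerance = 1e-9)
})
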