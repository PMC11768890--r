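# Shared fixtures built in code. Everything is deterministic under the
# seeds fixed here.

# Small standard generator config for fast end-to-end checks.
small_config <- function(seed = 1, ...) {
  synth_config(n_genes = 400, n_metabolites = 60, n_modules_expr = 2,
               n_modules_met = 2, seed = seed, ...)
}

# Counts with a known two-group structure on the log2 scale.
toy_two_group_matrix <- function(n_feat = 20, n_per_group = 4, delta = 2,
                                 sd = 0.1, seed = 42) {
  set.seed(seed)
  groups <- factor(rep(c("Ctrl", "TT"), each = n_per_group),
                   levels = c("Ctrl", "TT"))
  mat <- matrix(stats::rnorm(n_feat * 2 * n_per_group, sd = sd),
                n_feat, 2 * n_per_group)
  mat[, groups == "TT"] <- mat[, groups == "TT"] + delta
  rownames(mat) <- sprintf("f%02d", seq_len(n_feat))
  colnames(mat) <- paste0(groups, "_", sequence(rep(n_per_group, 2)))
  list(mat = mat, groups = groups)
}

# Five-group log-scale matrix with chosen per-group means for one gene
# replicated across features plus noise.
toy_five_group_matrix <- function(n_feat = 30, n_per_group = 4,
                                  means = c(Ctrl = 0, TT = 1, CQA = 1,
                                            TTCQA = 3, CAW = 2),
                                  sd = 0.3, seed = 7) {
  set.seed(seed)
  groups <- factor(rep(names(means), each = n_per_group),
                   levels = names(means))
  mat <- matrix(stats::rnorm(n_feat * length(groups), sd = sd),
                n_feat, length(groups))
  mat <- sweep(mat, 2, means[as.character(groups)], `+`)
  rownames(mat) <- sprintf("f%02d", seq_len(n_feat))
  colnames(mat) <- paste0(groups, "_", sequence(rep(n_per_group, 5)))
  list(mat = mat, groups = groups)
}

# Undirected toy graph from an edge list matrix (2 columns of names).
toy_graph <- function(edges) {
  igraph::graph_from_edgelist(as.matrix(edges), directed = FALSE)
}

# Brute-force triple-loop TOM, the independent oracle for
# tom_similarity().
tom_bruteforce <- function(A) {
  n <- nrow(A)
  diag(A) <- 1
  out <- matrix(1, n, n)
  k <- rowSums(A) - 1
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      l <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) l <- l + A[i, u] * A[u, j]
      }
      out[i, j] <- (l + A[i, j]) / (min(k[i], k[j]) + 1 - A[i, j])
    }
  }
  out
}

# Exhaustive hypergeometric upper-tail probability by enumerating all
# C(N, n) draws; feasible for N <= 15.
hyper_enumerate <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  in_set <- seq_len(K)
  hits <- apply(draws, 2, function(d) sum(d %in% in_set))
  mean(hits >= k)
}

# Exhaustive minimum Steiner-connector count: smallest number of
# non-seed nodes whose addition makes all seeds connected.
steiner_optimum <- function(graph, seeds) {
  vn <- igraph::V(graph)$name
  others <- setdiff(vn, seeds)
  for (m in 0:length(others)) {
    combs <- if (m == 0) list(character(0))
    else asplit(utils::combn(others, m), 2)
    for (add in combs) {
      sub <- igraph::induced_subgraph(graph, c(seeds, add))
      if (igraph::components(sub)$no == 1) return(m)
    }
  }
  Inf
}
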