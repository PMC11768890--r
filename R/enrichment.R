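#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test P[X >= k] of the overlap k between a
#' query feature set (size n) and each annotated set (size K) within a
#' universe of size N, with Benjamini-Hochberg adjustment across the
#' tested sets. Sets overlapping the query in fewer than
#' \code{min_overlap} features are reported but excluded from testing
#' (q = NA, tested = FALSE).
#'
#' @param query character vector, subset of \code{universe}.
#' @param gene_sets named list of character vectors; members are
#'   intersected with the universe.
#' @param universe character vector of all testable features.
#' @param q_threshold FDR cutoff used for the \code{significant} flag.
#' @param min_overlap minimum overlap to include a set in testing
#'   (default 2).
#' @return data.frame: set, k (overlap), n (query size), K (set size),
#'   N (universe size), p, q, tested, significant, overlap (members,
#'   comma separated).
#' @export
hypergeom_ora <- function(query, gene_sets, universe, q_threshold = 0.05,
                          min_overlap = 2) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  query <- unique(intersect(query, universe))
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- unique(intersect(gene_sets[[nm]], universe))
    K <- length(set)
    ov <- intersect(query, set)
    k <- length(ov)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, n = n, K = K, N = N, p = p,
               tested = k >= min_overlap,
               overlap = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  out$q[out$tested] <- stats::p.adjust(out$p[out$tested], method = "BH")
  out$significant <- !is.na(out$q) & out$q <= q_threshold
  out[, c("set", "k", "n", "K", "N", "p", "q", "tested", "significant",
          "overlap")]
}
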