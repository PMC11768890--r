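#' Load a STRING-dialect protein interaction edge list
#'
#' Reads a TSV with columns protein1, protein2, combined_score (integer
#' confidence on a 0-1000 scale), drops self-loops, merges duplicate
#' undirected edges keeping the maximum score, and retains edges at or
#' above \code{min_score}.
#'
#' @param path edge list file.
#' @param min_score confidence threshold (default 400, moderate-to-high
#'   confidence).
#' @return Undirected \code{igraph} graph with edge attribute
#'   \code{score}.
#' @export
load_string_edges <- function(path, min_score = 400) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("protein1", "protein2", "combined_score")
  if (!all(need %in% names(df)))
    stop("edge list must have columns: ", paste(need, collapse = ", "))
  bad <- which(!is.finite(df$combined_score) | df$combined_score < 0 |
                 df$combined_score > 1000)
  if (length(bad))
    stop("malformed score at line(s): ",
         paste(utils::head(bad + 1L, 5), collapse = ", "))
  ppi_graph(df, min_score = min_score)
}

#' Build a scored PPI graph from an edge data.frame
#'
#' @param df data.frame with protein1, protein2, combined_score.
#' @param min_score confidence threshold.
#' @return Undirected deduplicated \code{igraph} graph.
#' @export
ppi_graph <- function(df, min_score = 400) {
  df <- df[df$protein1 != df$protein2, , drop = FALSE]
  key <- ifelse(df$protein1 < df$protein2,
                paste(df$protein1, df$protein2),
                paste(df$protein2, df$protein1))
  o <- order(key, -df$combined_score)
  df <- df[o, , drop = FALSE][!duplicated(key[o]), , drop = FALSE]
  df <- df[df$combined_score >= min_score, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = df$protein1, to = df$protein2,
               score = df$combined_score),
    directed = FALSE)
  g
}

#' Seed-induced subnetwork with minimal connector insertion
#'
#' Induces the subgraph on the mapped seed nodes and, when
#' \code{allow_connectors}, approximates the smallest network still
#' containing as many seeds as possible by a Steiner-style heuristic:
#' repeatedly join the two largest seed-containing components through the
#' shortest connecting path in the full graph (ties broken by fewer added
#' nodes, then lexicographically by path node names) until no connecting
#' path of length at most \code{max_path_len} remains.
#'
#' @param graph full \code{igraph} graph.
#' @param seeds character vector of seed node names; unmapped seeds are
#'   reported in the result.
#' @param allow_connectors add non-seed connector nodes (default TRUE).
#' @param max_path_len longest allowed connecting path (edges; default 3).
#' @return List: \code{subgraph}, \code{seeds} (mapped), \code{unmapped},
#'   \code{connectors} (added node names), \code{connector_provenance}
#'   (data.frame connector / joins).
#' @export
seed_subnetwork <- function(graph, seeds, allow_connectors = TRUE,
                            max_path_len = 3) {
  vn <- igraph::V(graph)$name
  mapped <- intersect(unique(seeds), vn)
  unmapped <- setdiff(unique(seeds), vn)
  if (!length(mapped)) stop("no seeds map to the graph")
  nodes <- mapped
  provenance <- data.frame(connector = character(0), joins = character(0),
                           stringsAsFactors = FALSE)

  if (allow_connectors) {
    ## distances once over the current node set against the full graph;
    ## recomputed only when connector nodes are added
    D <- igraph::distances(graph, v = nodes, to = nodes)
    repeat {
      sub <- igraph::induced_subgraph(graph, nodes)
      comp <- igraph::components(sub)
      if (comp$no < 2) break
      memb <- comp$membership[nodes]   # align to `nodes` order
      seed_count <- vapply(seq_len(comp$no), function(ci)
        sum(nodes[memb == ci] %in% mapped), integer(1))
      ord <- order(-seed_count, -comp$csize)
      joined <- FALSE
      for (i in seq_len(comp$no - 1)) {
        for (j in (i + 1):comp$no) {
          ai <- which(memb == ord[i]); bj <- which(memb == ord[j])
          d <- D[ai, bj, drop = FALSE]
          dmin <- suppressWarnings(min(d))
          if (!is.finite(dmin) || dmin > max_path_len) next
          ## best connecting path: shortest, then lexicographic endpoints
          idx <- which(d == dmin, arr.ind = TRUE)
          pairs <- data.frame(from = nodes[ai[idx[, 1]]],
                              to = nodes[bj[idx[, 2]]],
                              stringsAsFactors = FALSE)
          pairs <- pairs[order(pairs$from, pairs$to), , drop = FALSE]
          best <- pairs[1, ]
          path <- igraph::shortest_paths(graph, from = best$from,
                                         to = best$to)$vpath[[1]]
          pn <- igraph::V(graph)$name[path]
          new <- setdiff(pn, nodes)
          nodes <- c(nodes, new)   # append so D indexing stays aligned
          if (length(new)) {
            provenance <- rbind(provenance, data.frame(
              connector = new,
              joins = paste(best$from, best$to, sep = "|"),
              stringsAsFactors = FALSE))
            dn <- igraph::distances(graph, v = new, to = nodes)
            D <- rbind(cbind(D, t(dn[, seq_len(ncol(D)), drop = FALSE])),
                       dn)
          }
          joined <- TRUE
          break
        }
        if (joined) break
      }
      if (!joined) break
    }
  }
  sub <- igraph::induced_subgraph(graph, nodes)
  list(subgraph = sub, seeds = mapped, unmapped = unmapped,
       connectors = setdiff(nodes, mapped),
       connector_provenance = provenance)
}

#' Bipartite metabolite-gene layer for seed metabolites
#'
#' @param met_gene data.frame with columns metabolite, gene.
#' @param seed_metabolites character vector of seed metabolite ids.
#' @return List: \code{edges} (the retained bipartite edges),
#'   \code{isolated} (seed metabolites with no partner gene),
#'   \code{genes} (partner genes), \code{unmapped}.
#' @export
metabolite_gene_layer <- function(met_gene, seed_metabolites) {
  stopifnot(all(c("metabolite", "gene") %in% names(met_gene)))
  seeds <- unique(seed_metabolites)
  known <- unique(met_gene$metabolite)
  unmapped <- setdiff(seeds, known)
  edges <- met_gene[met_gene$metabolite %in% seeds, , drop = FALSE]
  rownames(edges) <- NULL
  isolated <- setdiff(intersect(seeds, known),
                      unique(edges$metabolite))
  list(edges = edges, genes = unique(edges$gene),
       isolated = union(isolated, unmapped), unmapped = unmapped)
}

#' Compose the three network layers into one composite network
#'
#' Node-keyed union of the primary (seed-gene) PPI, the metabolite-gene
#' bipartite layer, and the secondary PPI built over the bipartite
#' partner genes. Shared gene nodes merge; each edge carries its layer
#' tag and each node a role: \code{seed_gene}, \code{seed_metabolite},
#' \code{connector_gene}, or \code{knowledge_gene} (a non-seed partner
#' gene from the knowledge base).
#'
#' @param ppi_primary \code{\link{seed_subnetwork}} result over the seed
#'   genes.
#' @param met_layer \code{\link{metabolite_gene_layer}} result.
#' @param ppi_secondary \code{\link{seed_subnetwork}} result over the
#'   metabolite partner genes (or NULL when there are none).
#' @param seed_genes,seed_metabolites the original seed id vectors.
#' @return List with \code{graph} (igraph, node attribute \code{role},
#'   edge attribute \code{layer}), \code{nodes}, \code{edges}
#'   data.frames.
#' @export
compose_layers <- function(ppi_primary, met_layer, ppi_secondary,
                           seed_genes, seed_metabolites) {
  edge_df <- function(g, layer) {
    if (is.null(g) || igraph::ecount(g) == 0)
      return(data.frame(from = character(0), to = character(0),
                        layer = character(0), stringsAsFactors = FALSE))
    el <- igraph::as_edgelist(g)
    data.frame(from = el[, 1], to = el[, 2], layer = layer,
               stringsAsFactors = FALSE)
  }
  e1 <- edge_df(ppi_primary$subgraph, "ppi_primary")
  e2 <- if (nrow(met_layer$edges)) {
    data.frame(from = met_layer$edges$metabolite, to = met_layer$edges$gene,
               layer = "met_gene", stringsAsFactors = FALSE)
  } else {
    data.frame(from = character(0), to = character(0), layer = character(0),
               stringsAsFactors = FALSE)
  }
  e3 <- if (!is.null(ppi_secondary)) edge_df(ppi_secondary$subgraph,
                                             "ppi_secondary")
  else e1[0, ]
  edges <- rbind(e1, e2, e3)
  ## dedup identical undirected edges within the same layer
  key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to),
               edges$layer)
  edges <- edges[!duplicated(key), , drop = FALSE]
  rownames(edges) <- NULL

  node_names <- unique(c(edges$from, edges$to,
                         ppi_primary$seeds,
                         intersect(seed_metabolites,
                                   met_layer$edges$metabolite)))
  connectors <- unique(c(ppi_primary$connectors,
                         if (!is.null(ppi_secondary)) ppi_secondary$connectors))
  role <- ifelse(node_names %in% seed_metabolites, "seed_metabolite",
                 ifelse(node_names %in% seed_genes, "seed_gene",
                        ifelse(node_names %in% connectors, "connector_gene",
                               "knowledge_gene")))
  nodes <- data.frame(name = node_names, role = role,
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  list(graph = g, nodes = nodes, edges = edges)
}

#' Random-walk (Walktrap) community detection
#'
#' Agglomerative community detection from t-step random-walk distances,
#' cut at maximum modularity. Graphs with fewer than 3 nodes form a
#' single community. The procedure is deterministic: the walk distances
#' are computed exactly from the transition matrix, not sampled.
#'
#' @param graph \code{igraph} graph.
#' @param steps walk length t (default 4).
#' @return Named integer vector of community labels.
#' @export
walktrap_communities <- function(graph, steps = 4) {
  n <- igraph::vcount(graph)
  if (n < 3) {
    return(stats::setNames(rep(1L, n), igraph::V(graph)$name))
  }
  wt <- igraph::cluster_walktrap(graph, steps = steps)
  stats::setNames(as.integer(igraph::membership(wt)),
                  igraph::V(graph)$name)
}

#' Keep communities containing both seed kinds
#'
#' @param membership named community labels
#'   (\code{\link{walktrap_communities}}).
#' @param seed_genes,seed_metabolites seed id vectors.
#' @return data.frame per community: community, size, n_seed_genes,
#'   n_seed_metabolites, mixed; plus attribute-free member list in
#'   \code{members}.
#' @export
filter_mixed_communities <- function(membership, seed_genes,
                                     seed_metabolites) {
  comms <- sort(unique(membership))
  rows <- lapply(comms, function(cm) {
    members <- names(membership)[membership == cm]
    nsg <- sum(members %in% seed_genes)
    nsm <- sum(members %in% seed_metabolites)
    data.frame(community = cm, size = length(members),
               n_seed_genes = nsg, n_seed_metabolites = nsm,
               mixed = nsg >= 1 & nsm >= 1, stringsAsFactors = FALSE)
  })
  tally <- do.call(rbind, rows)
  members <- lapply(comms, function(cm) names(membership)[membership == cm])
  names(members) <- as.character(comms)
  list(tally = tally, members = members,
       mixed = tally$community[tally$mixed])
}

#' Pathway enrichment of mixed communities
#'
#' Runs \code{\link{hypergeom_ora}} over all gene nodes (seeds and
#' connectors alike) of each selected community.
#'
#' @param mixed \code{\link{filter_mixed_communities}} result.
#' @param gene_sets named list of pathway gene sets.
#' @param universe gene universe for the test.
#' @param communities which community ids to test (default the mixed
#'   ones).
#' @param ... passed to \code{\link{hypergeom_ora}}.
#' @return data.frame of enrichment rows tagged by community id.
#' @export
community_enrichment <- function(mixed, gene_sets, universe,
                                 communities = mixed$mixed, ...) {
  rows <- list()
  for (cm in communities) {
    genes <- intersect(mixed$members[[as.character(cm)]], universe)
    if (!length(genes)) {
      warning("community ", cm, " has no gene members in the universe")
      next
    }
    res <- hypergeom_ora(genes, gene_sets, universe, ...)
    res$community <- cm
    rows[[length(rows) + 1L]] <- res
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' Cross-treatment overlap of integration results
#'
#' Pairwise shared seed genes and shared enriched pathways (by set name)
#' between per-treatment community analyses.
#'
#' @param results named list, one element per treatment, each a list with
#'   \code{seed_genes} (character) and \code{pathways} (character set
#'   names of significant enrichments).
#' @return data.frame: treatment_a, treatment_b, shared_genes,
#'   n_shared_genes, shared_pathways, n_shared_pathways.
#' @export
cross_treatment_overlap <- function(results) {
  if (length(results) < 2) stop("need at least 2 treatments")
  nm <- names(results)
  rows <- list()
  for (i in seq_len(length(nm) - 1)) {
    for (j in (i + 1):length(nm)) {
      sg <- intersect(results[[i]]$seed_genes, results[[j]]$seed_genes)
      sp <- intersect(results[[i]]$pathways, results[[j]]$pathways)
      rows[[length(rows) + 1L]] <- data.frame(
        treatment_a = nm[i], treatment_b = nm[j],
        shared_genes = paste(sort(sg), collapse = ","),
        n_shared_genes = length(sg),
        shared_pathways = paste(sort(sp), collapse = ","),
        n_shared_pathways = length(sp),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
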