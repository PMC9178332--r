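#' Jaccard coefficient between two gene sets
#'
#' J(A, B) = |A intersect B| / |A union B|.
#'
#' @param a,b Character vectors of gene ids (at least one non-empty).
#' @return A number in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) stop("both sets are empty")
  length(intersect(a, b)) / u
}

#' Hypergeometric over-representation test for one gene module
#'
#' For every annotation term overlapping the module (k >= 1), computes the
#' upper-tail probability P[X >= k] with X ~ Hypergeometric(N, K, n), where
#' N is the universe size, K the term size within the universe and n the
#' module size within the universe. P-values are BH-adjusted across the
#' tested terms of the module.
#'
#' @param module A module list (`module_id`, `genes`, ...) from
#'   [extract_modules()], or a character vector of gene ids.
#' @param ann Annotation list (term id -> gene ids).
#' @param universe Character vector: the enrichment universe (typically the
#'   tested genes carrying at least one annotation).
#' @return A data.frame (`module_id`, `term_id`, `k`, `K`, `n`, `N`, `p`,
#'   `padj`) sorted by p ascending, ties broken by larger `k` then term id.
#' @export
hypergeom_enrich <- function(module, ann, universe) {
  if (length(universe) == 0L) stop("empty universe")
  if (is.list(module)) {
    genes <- module$genes
    mid <- module$module_id
  } else {
    genes <- module
    mid <- NA_character_
  }
  genes <- intersect(genes, universe)
  n <- length(genes)
  N <- length(universe)
  rows <- lapply(names(ann), function(tid) {
    term <- intersect(ann[[tid]], universe)
    k <- length(intersect(term, genes))
    if (k == 0L) return(NULL)
    K <- length(term)
    data.frame(module_id = mid, term_id = tid, k = k, K = K, n = n, N = N,
               p = stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    return(data.frame(module_id = character(0), term_id = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p = numeric(0), padj = numeric(0)))
  res$padj <- benjamini_hochberg(res$p)
  res[order(res$p, -res$k, res$term_id), , drop = FALSE]
}

#' Select the top enriched terms of a module
#'
#' @param results Enrichment data.frame from [hypergeom_enrich()].
#' @param limit Number of terms to keep (default 15).
#' @return The first `limit` rows after sorting by p ascending, ties broken
#'   by larger overlap k then lexical term id.
#' @export
top_terms <- function(results, limit = 15) {
  res <- results[order(results$p, -results$k, results$term_id), ,
                 drop = FALSE]
  utils::head(res, limit)
}

#' Build the GO functional network from per-module top terms
#'
#' One node per (term, module) pair — a term selected by several modules
#' appears once per module (node ids suffixed `@module`), so module colouring
#' stays unambiguous; `dedupe = TRUE` collapses such duplicates to the single
#' instance with the best p. Edges connect node pairs whose gene-set Jaccard
#' coefficient strictly exceeds `threshold` (default 0.2); duplicated terms
#' share a gene set and are therefore linked by J = 1 edges.
#'
#' @param top_by_module Named list (module id -> enrichment data.frame of the
#'   module's selected terms, as from [top_terms()]).
#' @param ann Annotation list giving each term's gene set.
#' @param threshold Jaccard edge threshold, strict (default 0.2).
#' @param dedupe Collapse multi-module terms to one node (default FALSE).
#' @return A list of class `go_network`: `nodes` (data.frame `node`, `term_id`,
#'   `module_id`, `p`), `edges` (data.frame `from`, `to`, `jaccard`),
#'   `adjacency` (0/1 matrix), and `graph` (igraph object).
#' @export
build_go_network <- function(top_by_module, ann, threshold = 0.2,
                             dedupe = FALSE) {
  nodes <- do.call(rbind, lapply(names(top_by_module), function(mid) {
    tt <- top_by_module[[mid]]
    if (is.null(tt) || nrow(tt) == 0L) return(NULL)
    data.frame(term_id = tt$term_id, module_id = mid, p = tt$p,
               stringsAsFactors = FALSE)
  }))
  if (is.null(nodes) || nrow(nodes) == 0L)
    stop("no terms supplied to build the network")
  if (dedupe) {
    nodes <- nodes[order(nodes$p), , drop = FALSE]
    nodes <- nodes[!duplicated(nodes$term_id), , drop = FALSE]
    nodes$node <- nodes$term_id
  } else {
    dup <- nodes$term_id %in% nodes$term_id[duplicated(nodes$term_id)]
    nodes$node <- ifelse(dup, paste0(nodes$term_id, "@", nodes$module_id),
                         nodes$term_id)
  }
  nodes <- nodes[order(nodes$node), c("node", "term_id", "module_id", "p")]
  rownames(nodes) <- NULL
  missing <- setdiff(nodes$term_id, names(ann))
  if (length(missing) > 0L)
    stop("term without annotation gene set: ", missing[1L])

  nn <- nrow(nodes)
  adj <- matrix(0, nn, nn, dimnames = list(nodes$node, nodes$node))
  edges <- list()
  gs <- lapply(nodes$term_id, function(t) unique(ann[[t]]))
  if (nn > 1L) {
    for (i in seq_len(nn - 1L)) {
      for (j in seq(i + 1L, nn)) {
        jc <- jaccard(gs[[i]], gs[[j]])
        if (jc > threshold) {
          adj[i, j] <- adj[j, i] <- 1
          edges[[length(edges) + 1L]] <-
            data.frame(from = nodes$node[i], to = nodes$node[j], jaccard = jc,
                       stringsAsFactors = FALSE)
        }
      }
    }
  }
  edges <- if (length(edges) > 0L) do.call(rbind, edges)
           else data.frame(from = character(0), to = character(0),
                           jaccard = numeric(0))
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$module_id <- nodes$module_id
  igraph::V(g)$term_id <- nodes$term_id
  igraph::V(g)$p <- nodes$p
  net <- list(nodes = nodes, edges = edges, adjacency = adj, graph = g,
              threshold = threshold)
  class(net) <- "go_network"
  net
}

#' Clustering-coefficient connectivity statistics of a GO network
#'
#' Per node: C_i = 2 e_i / (k_i (k_i - 1)), where e_i counts closed triangles
#' among the node and its neighbours and k_i is the degree; C_i is defined 0
#' when k_i < 2. Per module: intramodular connectivity C = mean of C_i over
#' the module's nodes, and extramodular connectivity = the sum over the
#' module's nodes of their degree toward nodes of other modules
#' (`total_degree = TRUE` uses full degrees instead).
#'
#' @param net A `go_network`.
#' @param total_degree Use total instead of cross-module degree for the
#'   extramodular statistic.
#' @return A list with `node_stats` (data.frame `node`, `module_id`,
#'   `degree`, `triangles`, `ci`) and `module_stats` (data.frame `module_id`,
#'   `n_nodes`, `c_mean`, `extramodular`).
#' @export
clustering_stats <- function(net, total_degree = FALSE) {
  adj <- net$adjacency
  nodes <- net$nodes
  if (nrow(nodes) == 0L) stop("network has no nodes")
  k <- rowSums(adj)
  # e_i: closed triangles through node i = (A^3)_ii / 2
  tri <- diag(adj %*% adj %*% adj) / 2
  ci <- ifelse(k < 2, 0, 2 * tri / (k * (k - 1)))
  node_stats <- data.frame(node = nodes$node, module_id = nodes$module_id,
                           degree = k, triangles = tri, ci = ci,
                           row.names = NULL, stringsAsFactors = FALSE)
  module_stats <- do.call(rbind, lapply(unique(nodes$module_id),
                                        function(mid) {
    in_mod <- nodes$module_id == mid
    cross <- sum(adj[in_mod, !in_mod, drop = FALSE])
    data.frame(module_id = mid, n_nodes = sum(in_mod),
               c_mean = mean(ci[in_mod]),
               extramodular = if (total_degree) sum(k[in_mod]) else cross,
               stringsAsFactors = FALSE)
  }))
  list(node_stats = node_stats, module_stats = module_stats)
}

#' Topological overlap matrix of a GO network
#'
#' Unsigned Ravasz-style overlap on the unweighted adjacency:
#' TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij) with
#' l_ij = sum_u a_iu a_uj, TOM_ii = 1, and TOM_ij = 0 when the denominator
#' vanishes (two non-adjacent nodes one of which is isolated).
#'
#' @param net A `go_network`, or a 0/1 adjacency matrix.
#' @return Symmetric numeric matrix in \[0, 1\] with unit diagonal.
#' @export
topological_overlap <- function(net) {
  adj <- if (inherits(net, "go_network")) net$adjacency else net
  k <- rowSums(adj)
  l <- adj %*% adj
  denom <- outer(k, k, pmin) + 1 - adj
  tom <- (l + adj) / denom
  tom[denom <= 0] <- 0
  diag(tom) <- 1
  tom
}

#' Cluster gene modules by topological overlap
#'
#' The dissimilarity between two modules is the mean of (1 - TOM_ij) over all
#' cross-module node pairs; average-linkage hierarchical clustering of this
#' matrix is cut into `n_clusters` groups.
#'
#' @param net A `go_network`.
#' @param tom Topological overlap matrix (computed from `net` if missing).
#' @param n_clusters Number of clusters to cut (default 4).
#' @return A list with `dissimilarity` (module x module matrix), `hclust`,
#'   and `clusters` (named integer vector of cluster labels per module).
#' @export
cluster_modules <- function(net, tom = NULL, n_clusters = 4) {
  if (is.null(tom)) tom <- topological_overlap(net)
  mods <- unique(net$nodes$module_id)
  if (length(mods) < n_clusters)
    stop("fewer modules (", length(mods), ") than clusters (", n_clusters, ")")
  dis <- matrix(0, length(mods), length(mods), dimnames = list(mods, mods))
  for (i in seq_along(mods)) {
    for (j in seq_along(mods)) {
      if (i == j) next
      a <- net$nodes$module_id == mods[i]
      b <- net$nodes$module_id == mods[j]
      dis[i, j] <- mean(1 - tom[a, b, drop = FALSE])
    }
  }
  dis <- (dis + t(dis)) / 2
  hc <- stats::hclust(stats::as.dist(dis), method = "average")
  clusters <- stats::cutree(hc, k = n_clusters)
  list(dissimilarity = dis, hclust = hc, clusters = clusters)
}
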