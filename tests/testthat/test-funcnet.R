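test_that("Jaccard coefficient on sets", {
  expect_equal(jaccard(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard(c("a", "b"), c("c", "d")), 0)
  expect_equal(jaccard(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_error(jaccard(character(0), character(0)), "empty")
  set.seed(1)
  for (i in 1:50) {
    a <- sample(letters, sample(1:15, 1))
    b <- sample(letters, sample(1:15, 1))
    expect_equal(jaccard(a, b), jaccard_oracle(a, b))
    expect_equal(jaccard(a, b), jaccard(b, a))  # symmetry
  }
})

test_that("hypergeometric enrichment matches exact enumeration", {
  # N=20, K=5, n=5, k=4 by direct summation
  universe <- paste0("g", 1:20)
  module <- universe[1:5]
  ann <- list(T1 = c(universe[1:4], "g20"),      # k=4, K=5
              T2 = universe[10:15],              # k=0: unreported
              T3 = universe[1:5])                # term == module
  res <- hypergeom_enrich(module, ann, universe)
  expect_false("T2" %in% res$term_id)
  expect_equal(res$p[res$term_id == "T1"], hyper_oracle(4, 5, 5, 20))
  expect_equal(res$p[res$term_id == "T3"], 1 / choose(20, 5))
  expect_true(all(res$padj >= res$p))
  expect_true(all(res$k <= pmin(res$K, res$n)))
  expect_error(hypergeom_enrich(module, ann, character(0)), "empty universe")
})

test_that("top_terms applies the p / overlap / lexical tie-break", {
  res <- data.frame(module_id = "M1",
                    term_id = c("T3", "T1", "T2", "T4"),
                    k = c(5L, 7L, 7L, 2L), K = 10L, n = 20L, N = 100L,
                    p = c(0.01, 0.002, 0.002, 0.5), padj = 1,
                    stringsAsFactors = FALSE)
  expect_identical(top_terms(res, 3)$term_id, c("T1", "T2", "T3"))
  expect_identical(top_terms(res, 10)$term_id, c("T1", "T2", "T3", "T4"))
  expect_equal(nrow(top_terms(res, 0)), 0)
})

test_that("network edges require Jaccard strictly above the threshold", {
  ann <- list(A = paste0("g", 1:10),
              B = paste0("g", 3:12),   # J(A,B) = 8/12 = 0.667
              C = paste0("g", 1:5),    # J(A,C) = 0.5, J(B,C) = 3/12 = 0.25
              D = paste0("g", 50:54))  # disjoint
  tops <- list(M1 = data.frame(term_id = c("A", "B"), p = c(1e-4, 1e-3)),
               M2 = data.frame(term_id = c("C", "D"), p = c(1e-4, 1e-3)))
  net <- build_go_network(tops, ann, threshold = 0.2)
  es <- net$edges
  pair <- function(x, y) any((es$from == x & es$to == y) |
                             (es$from == y & es$to == x))
  expect_true(pair("A", "B") && pair("A", "C") && pair("B", "C"))
  expect_equal(nrow(es), 3)
  # exact threshold: J = 0.25 with threshold 0.25 must NOT create an edge
  net2 <- build_go_network(tops, ann, threshold = 0.25)
  expect_false(any((net2$edges$from == "B" & net2$edges$to == "C") |
                   (net2$edges$from == "C" & net2$edges$to == "B")))
  # threshold 1: only identical gene sets would connect
  expect_equal(nrow(build_go_network(tops, ann, threshold = 1)$edges), 0)
  # a term picked by two modules appears once per module, joined by J = 1
  tops_dup <- list(M1 = data.frame(term_id = "A", p = 1e-4),
                   M2 = data.frame(term_id = "A", p = 1e-3))
  netd <- build_go_network(tops_dup, ann)
  expect_equal(nrow(netd$nodes), 2)
  expect_equal(netd$edges$jaccard, 1)
  netc <- build_go_network(tops_dup, ann, dedupe = TRUE)
  expect_equal(nrow(netc$nodes), 1)
  expect_identical(netc$nodes$module_id, "M1")  # best p wins
})

test_that("network construction is order-independent", {
  ann <- lapply(setNames(1:8, paste0("T", 1:8)),
                function(i) paste0("g", i:(i + 6)))
  set.seed(4)
  tops <- list(M1 = data.frame(term_id = paste0("T", 1:4), p = runif(4)),
               M2 = data.frame(term_id = paste0("T", 5:8), p = runif(4)))
  tops_rev <- lapply(tops, function(d) d[rev(seq_len(nrow(d))), ])[2:1]
  n1 <- build_go_network(tops, ann)
  n2 <- build_go_network(tops_rev, ann)
  key <- function(es) sort(paste(pmin(es$from, es$to), pmax(es$from, es$to)))
  expect_identical(key(n1$edges), key(n2$edges))
})

test_that("clustering coefficients match brute-force triangle counts", {
  # triangle: every node has C_i = 1
  tri <- matrix(1, 3, 3) - diag(3)
  dimnames(tri) <- list(paste0("n", 1:3), paste0("n", 1:3))
  net <- list(nodes = data.frame(node = rownames(tri), module_id = "M1",
                                 stringsAsFactors = FALSE),
              adjacency = tri)
  class(net) <- "go_network"
  cs <- clustering_stats(net)
  expect_equal(cs$node_stats$ci, rep(1, 3))
  expect_equal(cs$module_stats$c_mean, 1)
  # path a-b-c: no closed triangle anywhere
  path <- matrix(0, 3, 3, dimnames = dimnames(tri))
  path[1, 2] <- path[2, 1] <- path[2, 3] <- path[3, 2] <- 1
  net$adjacency <- path
  expect_equal(clustering_stats(net)$node_stats$ci, c(0, 0, 0))
  # random graphs vs the enumeration oracle and igraph
  set.seed(6)
  for (i in 1:30) {
    n <- sample(4:12, 1)
    adj <- random_adjacency(n)
    netr <- list(nodes = data.frame(node = rownames(adj),
                                    module_id = rep(c("M1", "M2"),
                                                    length.out = n),
                                    stringsAsFactors = FALSE),
                 adjacency = adj)
    class(netr) <- "go_network"
    got <- clustering_stats(netr)$node_stats$ci
    want <- vapply(seq_len(n), function(v) ci_oracle(adj, v), numeric(1))
    expect_equal(got, want)
    ig <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    ig_ci <- unname(igraph::transitivity(ig, type = "localundirected",
                                         isolates = "zero"))
    ig_ci[rowSums(adj) < 2] <- 0
    expect_equal(got, ig_ci)
  }
})

test_that("extramodular connectivity counts cross-module degree", {
  # 4 nodes: M1 = {a, b}, M2 = {c, d}; edges a-b, a-c, c-d
  adj <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  adj["a", "b"] <- adj["b", "a"] <- 1
  adj["a", "c"] <- adj["c", "a"] <- 1
  adj["c", "d"] <- adj["d", "c"] <- 1
  net <- list(nodes = data.frame(node = letters[1:4],
                                 module_id = c("M1", "M1", "M2", "M2"),
                                 stringsAsFactors = FALSE),
              adjacency = adj)
  class(net) <- "go_network"
  ms <- clustering_stats(net)$module_stats
  expect_equal(ms$extramodular, c(1, 1))  # only the a-c edge crosses
  ms_tot <- clustering_stats(net, total_degree = TRUE)$module_stats
  expect_equal(ms_tot$extramodular, c(3, 3))
})

test_that("topological overlap matches the formula and its bounds", {
  # clique: all TOM entries 1
  k4 <- matrix(1, 4, 4) - diag(4)
  dimnames(k4) <- list(paste0("n", 1:4), paste0("n", 1:4))
  expect_true(all(topological_overlap(k4) == 1))
  # isolated node: zero overlap with everyone
  adj <- matrix(0, 3, 3, dimnames = list(paste0("n", 1:3), paste0("n", 1:3)))
  adj[1, 2] <- adj[2, 1] <- 1
  tom <- topological_overlap(adj)
  expect_equal(tom[3, 1], 0)
  expect_equal(tom[3, 3], 1)
  # random graphs vs the loop oracle; bounds and symmetry
  set.seed(8)
  for (i in 1:30) {
    n <- sample(4:12, 1)
    a <- random_adjacency(n)
    tom <- topological_overlap(a)
    expect_equal(tom, t(tom))
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
    for (p in 1:4) {
      ij <- sample(n, 2)
      expect_equal(tom[ij[1], ij[2]], tom_oracle(a, ij[1], ij[2]))
    }
  }
})

test_that("module clustering recovers planted blocks", {
  # 6 modules, one node each, in 3 disconnected cliques of 2
  adj <- matrix(0, 6, 6, dimnames = list(paste0("n", 1:6), paste0("n", 1:6)))
  for (b in c(1, 3, 5)) adj[b, b + 1] <- adj[b + 1, b] <- 1
  net <- list(nodes = data.frame(node = rownames(adj),
                                 module_id = paste0("M", 1:6),
                                 stringsAsFactors = FALSE),
              adjacency = adj)
  class(net) <- "go_network"
  cl <- cluster_modules(net, n_clusters = 3)
  lab <- cl$clusters
  expect_equal(unname(lab[c("M1", "M3", "M5")]),
               unname(lab[c("M2", "M4", "M6")]))
  expect_equal(length(unique(lab)), 3)
  # as many clusters as modules: singletons
  expect_equal(length(unique(cluster_modules(net, n_clusters = 6)$clusters)),
               6)
  expect_error(cluster_modules(net, n_clusters = 7), "fewer modules")
})
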