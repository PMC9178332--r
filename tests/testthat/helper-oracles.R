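# Independent brute-force oracles, deliberately written as literal
# enumerations so they share no code path with the package.

# step-up BH straight from the definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    v <- Inf
    for (j in i:m) v <- min(v, m * ps[j] / j)
    adj[i] <- min(1, v)
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# hypergeometric upper tail by direct summation over the overlap
hyper_oracle <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# per-node clustering coefficient by explicit neighbour-pair enumeration
ci_oracle <- function(adj, i) {
  nb <- which(adj[i, ] > 0)
  k <- length(nb)
  if (k < 2) return(0)
  e <- 0
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      if (adj[nb[a], nb[b]] > 0) e <- e + 1
    }
  }
  2 * e / (k * (k - 1))
}

# topological overlap entry by explicit loops
tom_oracle <- function(adj, i, j) {
  if (i == j) return(1)
  l <- 0
  for (u in seq_len(nrow(adj))) l <- l + adj[i, u] * adj[u, j]
  k <- rowSums(adj)
  den <- min(k[i], k[j]) + 1 - adj[i, j]
  if (den <= 0) return(0)
  (l + adj[i, j]) / den
}

jaccard_oracle <- function(a, b) {
  inter <- sum(!is.na(match(unique(a), unique(b))))
  inter / (length(unique(a)) + length(unique(b)) - inter)
}

random_adjacency <- function(n, p_edge = 0.4) {
  adj <- matrix(0, n, n)
  adj[upper.tri(adj)] <- as.numeric(stats::runif(n * (n - 1) / 2) < p_edge)
  adj <- adj + t(adj)
  dimnames(adj) <- list(paste0("n", 1:n), paste0("n", 1:n))
  adj
}
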