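# Independent brute-force oracles for the graph metrics, written against the
# adjacency matrix directly (no igraph) so they share no code path with the
# implementation.

# Floyd-Warshall all-pairs shortest paths
oracle_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  d[a == 1] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# number of shortest paths s -> every node, by dynamic programming in order
# of increasing distance from s
oracle_sigma_from <- function(a, d, s) {
  n <- nrow(a)
  sigma <- numeric(n)
  sigma[s] <- 1
  ord <- order(d[s, ])
  for (u in ord) {
    if (u == s || !is.finite(d[s, u])) next
    preds <- which(a[u, ] == 1 & d[s, ] == d[s, u] - 1)
    sigma[u] <- sum(sigma[preds])
  }
  sigma
}

# betweenness via the path-counting identity:
# sigma_st(v) = [d(s,v) + d(v,t) == d(s,t)] * sigma_sv * sigma_vt
oracle_betweenness <- function(a, normalized = TRUE) {
  n <- nrow(a)
  d <- oracle_distances(a)
  sig <- t(vapply(seq_len(n), function(s) oracle_sigma_from(a, d, s),
                  numeric(n)))
  bc <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (!is.finite(d[s, t]) || d[s, t] == 0) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
            d[s, v] + d[v, t] == d[s, t]) {
          bc[v] <- bc[v] + sig[s, v] * sig[v, t] / sig[s, t]
        }
      }
    }
  }
  if (normalized && n > 2) bc <- bc / ((n - 1) * (n - 2) / 2)
  bc
}

oracle_degree <- function(a) as.integer(rowSums(a))

oracle_clustering <- function(a) {
  n <- nrow(a)
  vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    sum(a[nb, nb]) / 2 / (k * (k - 1) / 2)
  }, numeric(1))
}

oracle_global_efficiency <- function(a) {
  d <- oracle_distances(a)
  n <- nrow(a)
  inv <- 1 / d
  diag(inv) <- 0
  rowSums(inv) / (n - 1)
}

oracle_local_efficiency <- function(a) {
  n <- nrow(a)
  vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    dsub <- oracle_distances(a[nb, nb, drop = FALSE])
    inv <- 1 / dsub
    diag(inv) <- 0
    sum(inv) / (k * (k - 1))
  }, numeric(1))
}

oracle_apl <- function(a) {
  d <- oracle_distances(a)
  apply(d, 1, function(row) {
    reach <- row[is.finite(row) & row > 0]
    if (length(reach) == 0) NA_real_ else mean(reach)
  })
}
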