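# Small graphs and generated data used across test files.

adj_complete <- function(n) {
  a <- matrix(1L, n, n)
  diag(a) <- 0L
  a
}

adj_path <- function(n) {
  a <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) a[i, i + 1] <- a[i + 1, i] <- 1L
  a
}

adj_star <- function(n) {
  a <- matrix(0L, n, n)
  a[1, 2:n] <- a[2:n, 1] <- 1L
  a
}

# triangle a-b-c plus pendant d attached to a (a = node 1)
adj_triangle_pendant <- function() {
  a <- matrix(0L, 4, 4)
  a[1, 2] <- a[2, 1] <- 1L
  a[1, 3] <- a[3, 1] <- 1L
  a[2, 3] <- a[3, 2] <- 1L
  a[1, 4] <- a[4, 1] <- 1L
  a
}

adj_random <- function(n, p, seed) {
  set.seed(seed)
  a <- matrix(0L, n, n)
  up <- which(upper.tri(a))
  a[up] <- as.integer(stats::runif(length(up)) < p)
  a[lower.tri(a)] <- t(a)[lower.tri(a)]
  a
}

random_timeseries <- function(T_len = 50, R = 5, seed = 1) {
  set.seed(seed)
  roi_timeseries(matrix(stats::rnorm(T_len * R), T_len, R),
                 scan_id = paste0("rand", seed))
}

# a small scan pair whose metrics vary enough for the kernel null
small_test_pair <- function(seed = 1, planted = NULL, R = 48, T_len = 200) {
  spec <- make_block_covariance(R, 4, rho_in = 0.55, rho_out = 0.1)
  simulate_scan_pair(spec, planted, T_baseline = T_len, T_post = T_len,
                     seeds = c(seed, seed + 1L))
}

# shared state between acceptance blocks that reuse one simulation study
.acceptance_state <- new.env(parent = emptyenv())
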