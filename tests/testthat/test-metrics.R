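test_that("worked small-graph values are exact", {
  k4 <- binary_network(adj_complete(4))
  m <- compute_metrics(k4, "k4")
  expect_equal(m$D, rep(3L, 4))
  expect_equal(m$CC, rep(1, 4))
  expect_equal(m$BC, rep(0, 4))
  expect_equal(m$GE, rep(1, 4))
  expect_equal(m$LE, rep(1, 4))
  expect_equal(m$APL, rep(1, 4))
  expect_true(all(m$apl_defined))

  p3 <- binary_network(adj_path(3))
  mp <- compute_metrics(p3, "p3")
  expect_equal(mp$BC, c(0, 1, 0))          # single (1,3) pair routes via 2
  expect_equal(mp$GE, c(0.75, 1, 0.75))    # (1 + 1/2)/2 at the ends
  expect_equal(mp$APL, c(1.5, 1, 1.5))

  tp <- binary_network(adj_triangle_pendant())
  mt <- compute_metrics(tp, "tp")
  expect_equal(mt$CC[1], 1 / 3)            # one edge among 3 neighbor pairs
  expect_equal(mt$LE[1], 1 / 3)            # only the b-c pair is finite
  expect_equal(mt$CC[4], 0)                # pendant: degree 1
  expect_equal(mt$LE[4], 0)

  star <- binary_network(adj_star(5))
  ms <- compute_metrics(star, "star")
  expect_equal(ms$D, c(4L, 1L, 1L, 1L, 1L))
  expect_equal(ms$CC[1], 0)
  expect_equal(ms$LE[1], 0)
  expect_equal(ms$BC[1], 1)                # all leaf pairs route via center
})

test_that("disconnected and empty graphs follow the stated conventions", {
  # two disconnected dyads: cross-pair distances infinite
  dy <- matrix(0L, 4, 4)
  dy[1, 2] <- dy[2, 1] <- 1L
  dy[3, 4] <- dy[4, 3] <- 1L
  net <- binary_network(dy)
  d <- shortest_path_lengths(net)
  expect_true(all(is.infinite(d[1:2, 3:4])))
  m <- compute_metrics(net, "dyads")
  expect_equal(m$GE, rep(1 / 3, 4))        # one reachable peer of three
  expect_equal(m$APL, rep(1, 4))           # averaged over reachable only

  # empty graph: isolated-node conventions
  e <- binary_network(matrix(0L, 3, 3))
  me <- compute_metrics(e, "empty")
  expect_equal(me$D, rep(0L, 3))
  expect_equal(me$GE, rep(0, 3))
  expect_equal(me$BC, rep(0, 3))
  expect_true(all(is.na(me$APL)))
  expect_false(any(me$apl_defined))

  # node in a small component of a larger graph averages over its peers
  a <- matrix(0L, 10, 10)
  a[1, 2] <- a[2, 1] <- 1L
  a[2, 3] <- a[3, 2] <- 1L                 # component {1,2,3} as a path
  a[4:10, 4:10] <- adj_complete(7)
  net10 <- binary_network(a)
  m10 <- compute_metrics(net10, "mixed")
  expect_equal(m10$APL[1], 1.5)            # distances 1 and 2 in its component
})

test_that("all six metrics match brute-force oracles on random graphs", {
  set.seed(2024)
  for (i in 1:30) {
    n <- sample(4:12, 1)
    a <- adj_random(n, runif(1, 0.15, 0.7), seed = 5000 + i)
    net <- binary_network(a)
    expect_identical(node_degree(net), setNames(oracle_degree(a), net$labels))
    expect_equal(unname(clustering_coefficient(net)), oracle_clustering(a),
                 tolerance = 1e-12)
    expect_equal(unname(betweenness_centrality(net)), oracle_betweenness(a),
                 tolerance = 1e-12)
    expect_equal(unname(nodal_global_efficiency(net)),
                 oracle_global_efficiency(a), tolerance = 1e-12)
    expect_equal(unname(local_efficiency(net)), oracle_local_efficiency(a),
                 tolerance = 1e-12)
    expect_equal(unname(average_path_length(net)), oracle_apl(a),
                 tolerance = 1e-12)
    expect_equal(unname(shortest_path_lengths(net)), oracle_distances(a))
  }
})

test_that("degree sum equals twice the edge count (handshake identity)", {
  for (seed in 1:10) {
    a <- adj_random(9, 0.4, seed = seed)
    net <- binary_network(a)
    expect_equal(sum(node_degree(net)), sum(a))
  }
})

test_that("metrics are invariant under node permutation", {
  a <- adj_random(10, 0.35, seed = 77)
  net <- binary_network(a, labels = LETTERS[1:10])
  set.seed(8)
  perm <- sample(10)
  net_p <- binary_network(a[perm, perm], labels = LETTERS[1:10][perm])
  m <- compute_metrics(net)
  mp <- compute_metrics(net_p)
  ord <- match(m$name, mp$name)
  for (met in c("D", "CC", "BC", "GE", "LE", "APL")) {
    expect_equal(mp[[met]][ord], m[[met]], tolerance = 1e-12)
  }
})

test_that("adding an edge never decreases degree or nodal efficiency", {
  a <- adj_random(10, 0.25, seed = 31)
  net <- binary_network(a)
  ge0 <- nodal_global_efficiency(net)
  d0 <- node_degree(net)
  missing <- which(a == 0 & upper.tri(a), arr.ind = TRUE)
  for (k in seq_len(min(5, nrow(missing)))) {
    a2 <- a
    a2[missing[k, 1], missing[k, 2]] <- 1L
    a2[missing[k, 2], missing[k, 1]] <- 1L
    net2 <- binary_network(a2)
    expect_true(all(node_degree(net2) >= d0))
    expect_true(all(nodal_global_efficiency(net2) >= ge0 - 1e-14))
  }
})

test_that("clustering coefficient of every tree node is zero", {
  # spanning-tree style graph: path plus leaves
  a <- matrix(0L, 7, 7)
  edges <- rbind(c(1, 2), c(2, 3), c(3, 4), c(2, 5), c(3, 6), c(6, 7))
  for (i in seq_len(nrow(edges))) {
    a[edges[i, 1], edges[i, 2]] <- a[edges[i, 2], edges[i, 1]] <- 1L
  }
  expect_equal(unname(clustering_coefficient(binary_network(a))), rep(0, 7))
})
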