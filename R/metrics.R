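## Nodal graph metrics on a binary undirected network.
##
## Conventions for disconnected graphs: efficiencies use 1/Inf = 0; average
## path length is taken over reachable peers only and flagged undefined for
## isolated nodes; betweenness is normalized by (R-1)(R-2)/2 so that values
## are comparable across graph sizes.

as_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected",
                                      diag = FALSE)
}

#' All-pairs shortest-path hop counts
#'
#' @param net a `binary_network`.
#' @return symmetric R x R matrix of hop counts, `Inf` where unreachable,
#'   zero diagonal.
#' @export
shortest_path_lengths <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  d <- igraph::distances(as_igraph(net))
  dimnames(d) <- list(net$labels, net$labels)
  d
}

#' Node degree
#'
#' @param net a `binary_network`.
#' @return named integer vector of row sums of the adjacency matrix.
#' @export
node_degree <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  stats::setNames(as.integer(rowSums(net$adjacency)), net$labels)
}

#' Local clustering coefficient
#'
#' Fraction of a node's neighbor pairs that are themselves connected;
#' defined as 0 for nodes of degree 0 or 1.
#'
#' @param net a `binary_network`.
#' @return named numeric vector in \[0, 1\].
#' @export
clustering_coefficient <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  cc <- igraph::transitivity(as_igraph(net), type = "local", isolates = "zero")
  stats::setNames(cc, net$labels)
}

#' Betweenness centrality
#'
#' Brandes-style shortest-path counting: for node v, the sum over all
#' unordered pairs (s, t) not containing v of the fraction of s-t shortest
#' paths passing through v. Normalized by (R-1)(R-2)/2 so values lie in
#' \[0, 1\]; set `normalized = FALSE` for the raw pair counts.
#'
#' @param net a `binary_network`.
#' @param normalized divide by (R-1)(R-2)/2 (default TRUE).
#' @return named numeric vector.
#' @export
betweenness_centrality <- function(net, normalized = TRUE) {
  stopifnot(inherits(net, "binary_network"))
  b <- igraph::betweenness(as_igraph(net), directed = FALSE)
  R <- length(net$labels)
  if (normalized && R > 2L) b <- b / ((R - 1) * (R - 2) / 2)
  if (normalized && R <= 2L) b[] <- 0
  stats::setNames(b, net$labels)
}

#' Nodal global efficiency
#'
#' `GE(i) = mean over j != i of 1/d_ij`, with 1/Inf = 0 for unreachable
#' pairs. This is the per-node decomposition of global efficiency (the
#' whole-graph scalar is its average), reported per ROI.
#'
#' @param net a `binary_network`.
#' @param dist optional precomputed output of [shortest_path_lengths()].
#' @return named numeric vector in \[0, 1\].
#' @export
nodal_global_efficiency <- function(net, dist = NULL) {
  stopifnot(inherits(net, "binary_network"))
  if (is.null(dist)) dist <- shortest_path_lengths(net)
  R <- nrow(dist)
  inv <- 1 / dist
  diag(inv) <- 0
  stats::setNames(rowSums(inv) / (R - 1), net$labels)
}

#' Local efficiency
#'
#' Efficiency of the subgraph induced by a node's neighbors (the node
#' itself removed): `LE(i) = (1/(k_i (k_i - 1))) * sum over ordered
#' neighbor pairs (j, h) of 1/d_jh` with distances measured inside the
#' neighbor subgraph. Zero for degree <= 1.
#'
#' @param net a `binary_network`.
#' @return named numeric vector in \[0, 1\].
#' @export
local_efficiency <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  a <- net$adjacency
  R <- nrow(a)
  le <- numeric(R)
  for (i in seq_len(R)) {
    nb <- which(a[i, ] == 1L)
    k <- length(nb)
    if (k < 2L) next
    sub <- binary_network(a[nb, nb, drop = FALSE], labels = net$labels[nb])
    dsub <- shortest_path_lengths(sub)
    inv <- 1 / dsub
    diag(inv) <- 0
    le[i] <- sum(inv) / (k * (k - 1))
  }
  stats::setNames(le, net$labels)
}

#' Per-node average path length
#'
#' Mean shortest-path hop count from node i to the nodes reachable from it.
#' Undefined (NA, with `apl_defined = FALSE` in [compute_metrics()]) for
#' isolated nodes.
#'
#' @param net a `binary_network`.
#' @param dist optional precomputed output of [shortest_path_lengths()].
#' @return named numeric vector (NA where undefined).
#' @export
average_path_length <- function(net, dist = NULL) {
  stopifnot(inherits(net, "binary_network"))
  if (is.null(dist)) dist <- shortest_path_lengths(net)
  apl <- apply(dist, 1L, function(row) {
    reach <- row[is.finite(row) & row > 0]
    if (length(reach) == 0L) NA_real_ else mean(reach)
  })
  stats::setNames(apl, net$labels)
}

#' Compute all six nodal metrics for one scan
#'
#' @param net a `binary_network`.
#' @param scan_id identifier recorded in the table.
#' @return data.frame (one row per ROI) with columns `index` (0-based),
#'   `name`, `D`, `CC`, `BC`, `GE`, `LE`, `APL`, `apl_defined`, `scan_id`.
#' @export
compute_metrics <- function(net, scan_id = "scan") {
  stopifnot(inherits(net, "binary_network"))
  dist <- shortest_path_lengths(net)
  apl <- average_path_length(net, dist)
  data.frame(
    index = seq_along(net$labels) - 1L,
    name = net$labels,
    D = node_degree(net),
    CC = clustering_coefficient(net),
    BC = betweenness_centrality(net),
    GE = nodal_global_efficiency(net, dist),
    LE = local_efficiency(net),
    APL = unname(apl),
    apl_defined = !is.na(apl),
    scan_id = scan_id,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

metric_names <- function() c("D", "CC", "BC", "GE", "LE", "APL")
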