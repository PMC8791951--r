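#' ROI-ROI Pearson correlation matrix
#'
#' Computes the full pairwise Pearson product-moment correlation matrix of
#' an ROI time series. Constant (zero-variance) ROI columns are an input
#' error: silently reporting r = 0 for them would fabricate the absence of
#' edges in the thresholded network.
#'
#' @param ts an [roi_timeseries()].
#' @return An object of class `correlation_matrix`: list with `values`
#'   (symmetric R x R matrix, unit diagonal), `n_samples` (number of time
#'   points), `labels`.
#' @export
correlation_matrix <- function(ts) {
  stopifnot(inherits(ts, "roi_timeseries"))
  x <- ts$data
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance ROI column(s): ",
         paste(ts$labels[sds == 0], collapse = ", "),
         " (correlation undefined)")
  }
  r <- stats::cor(x)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  structure(list(values = r, n_samples = nrow(x), labels = ts$labels),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  off <- x$values[upper.tri(x$values)]
  cat("Correlation matrix: ", length(x$labels), " ROIs, N = ", x$n_samples,
      ", |r| range ", sprintf("%.3f-%.3f", min(abs(off)), max(abs(off))), "\n",
      sep = "")
  invisible(x)
}

#' Analytic significance of a Pearson correlation
#'
#' Transforms r to `t = r * sqrt((n - 2) / (1 - r^2))` and evaluates the
#' Student-t tail with n - 2 degrees of freedom. The default is the
#' one-sided upper-tail probability: for r = 0.5 and n = 273 this gives
#' 5.64e-19, whereas the conventional two-sided test (available via
#' `sided = "two"`) gives twice that.
#'
#' @param r correlation value, |r| < 1.
#' @param n number of samples (time points), n >= 3. Vectorized over `r`
#'   and `n`.
#' @param sided `"one"` (upper tail, default) or `"two"`.
#' @return probability (vectorized).
#' @export
correlation_p_value <- function(r, n, sided = c("one", "two")) {
  sided <- match.arg(sided)
  if (any(!is.finite(r)) || any(abs(r) >= 1)) {
    stop("|r| must be < 1 (p is 0 in the limit; handle |r| = 1 upstream)")
  }
  if (any(n < 3)) stop("need n >= 3")
  tval <- r * sqrt((n - 2) / (1 - r^2))
  p <- stats::pt(tval, df = n - 2, lower.tail = FALSE)
  if (sided == "two") p <- 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
  p
}

#' Threshold a correlation matrix into a binary undirected network
#'
#' An edge (i, j) is present iff `r_ij > tau` or `r_ij < -tau` — strict
#' inequalities, so entries exactly at the cutoff are excluded. The sign of
#' each surviving correlation is kept in a side-channel matrix for audit but
#' is never used by the graph metrics.
#'
#' @param C a [correlation_matrix()].
#' @param tau correlation cutoff in (0, 1); default 0.5.
#' @return An object of class `binary_network`: list with `adjacency`
#'   (symmetric hollow 0/1 matrix), `signs` (sign of r on surviving edges,
#'   0 elsewhere), `threshold`, `labels`.
#' @export
threshold_network <- function(C, tau = 0.5) {
  stopifnot(inherits(C, "correlation_matrix"))
  if (!(tau > 0 && tau < 1)) stop("tau must be in (0, 1)")
  a <- (abs(C$values) > tau) * 1L
  diag(a) <- 0L
  sgn <- sign(C$values) * a
  diag(sgn) <- 0
  dimnames(a) <- dimnames(sgn) <- list(C$labels, C$labels)
  structure(list(adjacency = a, signs = sgn, threshold = tau,
                 labels = C$labels),
            class = "binary_network")
}

#' Construct a binary network directly from an adjacency matrix
#'
#' Convenience constructor used by tests and simulations.
#'
#' @param adjacency symmetric 0/1 matrix with zero diagonal.
#' @param labels optional node labels.
#' @param threshold cutoff recorded as metadata.
#' @return `binary_network` object.
#' @export
binary_network <- function(adjacency, labels = NULL, threshold = NA_real_) {
  a <- as.matrix(adjacency)
  if (nrow(a) != ncol(a)) stop("adjacency must be square")
  if (!all(a %in% c(0, 1))) stop("adjacency entries must be 0/1")
  if (!isTRUE(all.equal(a, t(a)))) stop("adjacency must be symmetric")
  if (any(diag(a) != 0)) stop("adjacency must be hollow (no self-loops)")
  storage.mode(a) <- "integer"
  if (is.null(labels)) labels <- sprintf("ROI_%04d", seq_len(nrow(a)))
  dimnames(a) <- list(labels, labels)
  structure(list(adjacency = a, signs = a, threshold = threshold,
                 labels = labels),
            class = "binary_network")
}

#' @export
print.binary_network <- function(x, ...) {
  ec <- sum(x$adjacency) / 2
  cat("Binary network: ", length(x$labels), " nodes, ", ec, " edges",
      if (!is.na(x$threshold)) sprintf(" (|r| > %g)", x$threshold) else "",
      "\n", sep = "")
  invisible(x)
}

#' Edge list of a binary network
#'
#' @param net a `binary_network`.
#' @param C optional `correlation_matrix` from which the network was
#'   thresholded; adds the r value per edge.
#' @return data.frame with columns roi_i, roi_j, sign and (if `C` given) r.
#' @export
network_edge_list <- function(net, C = NULL) {
  stopifnot(inherits(net, "binary_network"))
  idx <- which(net$adjacency == 1L & upper.tri(net$adjacency), arr.ind = TRUE)
  out <- data.frame(roi_i = net$labels[idx[, 1L]],
                    roi_j = net$labels[idx[, 2L]],
                    sign = net$signs[idx],
                    stringsAsFactors = FALSE)
  if (!is.null(C)) out$r <- C$values[idx]
  out
}
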