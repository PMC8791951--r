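## Synthetic paired-scan generator. Real resting-state BOLD is neither
## Gaussian nor white, but the pipeline's network construction depends only
## on second moments, so a zero-mean multivariate Gaussian with a
## block-constant correlation structure and AR(1) temporal smoothing is the
## minimal model that exercises every stage. Defaults (132 ROIs in 6 blocks
## of 22, rho_in = 0.65, rho_out = 0.1, T = 273) put the |r| > 0.5
## threshold in the regime of dense within-block, sparse between-block
## networks.

#' Block-constant covariance specification
#'
#' Correlation is `rho_in` within a block and `rho_out` between blocks,
#' scaled by per-ROI variances. Positive definiteness is verified by a
#' Cholesky factorization at construction.
#'
#' @param R ROI count.
#' @param n_blocks number of equal-size-as-possible blocks.
#' @param rho_in within-block correlation, `rho_out <= rho_in < 1`.
#' @param rho_out between-block correlation, `> -1`.
#' @param variances per-ROI variances (default 1).
#' @param labels optional ROI names.
#' @return object of class `covariance_spec`: list with `R`,
#'   `block_assignment`, `rho_in`, `rho_out`, `variances`, `labels`,
#'   `sigma` (the R x R covariance matrix).
#' @export
make_block_covariance <- function(R, n_blocks, rho_in, rho_out,
                                  variances = rep(1, R), labels = NULL) {
  if (!(rho_out > -1 && rho_out <= rho_in && rho_in < 1)) {
    stop("need -1 < rho_out <= rho_in < 1")
  }
  if (length(variances) != R || any(variances <= 0)) {
    stop("variances must be length R and positive")
  }
  block <- sort(rep(seq_len(n_blocks), length.out = R))
  corr <- matrix(rho_out, R, R)
  for (b in seq_len(n_blocks)) {
    in_b <- block == b
    corr[in_b, in_b] <- rho_in
  }
  diag(corr) <- 1
  if (is.null(labels)) labels <- sprintf("ROI_%04d", seq_len(R))
  spec <- structure(list(R = R, block_assignment = block, rho_in = rho_in,
                         rho_out = rho_out, variances = variances,
                         labels = labels,
                         sigma = diag(sqrt(variances)) %*% corr %*% diag(sqrt(variances))),
                    class = "covariance_spec")
  check_pd(spec$sigma)
  spec
}

check_pd <- function(sigma) {
  ok <- tryCatch({ chol(sigma); TRUE }, error = function(e) FALSE)
  if (!ok) stop("covariance is not positive definite; use smaller |rho| or delta")
  invisible(TRUE)
}

#' Plant a connectivity change into a covariance spec
#'
#' Modes: `detach` lowers each target ROI's correlation with the rest of
#' its own block by `delta` (delta = rho_in severs it completely);
#' `attach` raises each target's correlation with the ROIs of `to_block`
#' by `delta`; `reassign` moves the target into `to_block` (its
#' correlations become rho_out to the old block and rho_in to the new).
#' All other entries are untouched; the result must remain positive
#' definite.
#'
#' @param spec a `covariance_spec`.
#' @param target_rois integer indices (1-based) of the ROIs to change.
#' @param mode `"detach"`, `"attach"` or `"reassign"`.
#' @param delta correlation change (ignored for `reassign`).
#' @param to_block destination block for `attach`/`reassign`.
#' @return a new `covariance_spec` carrying a `planted` attribute that
#'   records the change.
#' @export
apply_planted_change <- function(spec, target_rois,
                                 mode = c("detach", "attach", "reassign"),
                                 delta = NULL, to_block = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "covariance_spec"))
  if (any(target_rois < 1 | target_rois > spec$R)) stop("target ROI out of range")
  sd_vec <- sqrt(spec$variances)
  corr <- spec$sigma / tcrossprod(sd_vec)
  block <- spec$block_assignment
  for (t in target_rois) {
    if (mode == "detach") {
      if (is.null(delta)) stop("detach needs delta")
      peers <- which(block == block[t] & seq_len(spec$R) != t)
      corr[t, peers] <- corr[t, peers] - delta
      corr[peers, t] <- corr[t, peers]
    } else if (mode == "attach") {
      if (is.null(delta) || is.null(to_block)) stop("attach needs delta and to_block")
      peers <- which(block == to_block & seq_len(spec$R) != t)
      corr[t, peers] <- corr[t, peers] + delta
      corr[peers, t] <- corr[t, peers]
    } else {
      if (is.null(to_block)) stop("reassign needs to_block")
      old <- which(block == block[t] & seq_len(spec$R) != t)
      new <- which(block == to_block & seq_len(spec$R) != t)
      corr[t, old] <- spec$rho_out; corr[old, t] <- spec$rho_out
      corr[t, new] <- spec$rho_in;  corr[new, t] <- spec$rho_in
      block[t] <- to_block
    }
  }
  diag(corr) <- 1
  out <- spec
  out$block_assignment <- block
  out$sigma <- diag(sd_vec) %*% corr %*% diag(sd_vec)
  check_pd(out$sigma)
  attr(out, "planted") <- list(target_rois = target_rois, mode = mode,
                               delta = delta, to_block = to_block)
  out
}

#' Simulate one scan's ROI time series
#'
#' Zero-mean multivariate Gaussian with the spec's cross-ROI covariance and
#' optional AR(1) temporal autocorrelation. The AR recursion
#' `x_t = a x_{t-1} + sqrt(1 - a^2) e_t` with innovations `e_t ~ N(0, Sigma)`
#' and a stationary start leaves the cross-ROI covariance equal to Sigma at
#' every time point, while shrinking the effective number of independent
#' volumes — the feature of real fMRI that stresses the correlation
#' p-value machinery.
#'
#' @param spec a `covariance_spec`.
#' @param T_len number of time points (>= 3).
#' @param ar_coeff AR(1) coefficient in \[0, 1).
#' @param seed integer seed.
#' @param scan_id identifier for the result.
#' @return an [roi_timeseries()].
#' @export
simulate_scan <- function(spec, T_len, ar_coeff = 0, seed = NULL,
                          scan_id = "synthetic") {
  stopifnot(inherits(spec, "covariance_spec"))
  if (T_len < 3L) stop("need T >= 3")
  if (!(ar_coeff >= 0 && ar_coeff < 1)) stop("ar_coeff must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  L <- chol(spec$sigma)
  innov <- matrix(stats::rnorm(T_len * spec$R), T_len, spec$R) %*% L
  if (ar_coeff > 0) {
    x <- matrix(0, T_len, spec$R)
    x[1L, ] <- innov[1L, ]  # stationary start: marginal variance Sigma
    s <- sqrt(1 - ar_coeff^2)
    for (t in 2:T_len) x[t, ] <- ar_coeff * x[t - 1L, ] + s * innov[t, ]
  } else {
    x <- innov
  }
  roi_timeseries(x, labels = spec$labels, scan_id = scan_id)
}

#' Simulate a paired baseline/post scan set with planted changes
#'
#' The baseline scan is drawn from `baseline_spec`; the post scan from the
#' spec after applying each change in `planted` (a list of argument lists
#' for [apply_planted_change()], or `NULL` for a null pair). The ground
#' truth of what was planted travels with the result.
#'
#' @param baseline_spec a `covariance_spec`.
#' @param planted list of lists with elements `target_rois`, `mode`,
#'   `delta`, `to_block`; `NULL` or `list()` for a null pair.
#' @param T_baseline,T_post time points per scan (may differ, emulating
#'   differing per-scan effective N).
#' @param ar_coeff AR(1) coefficient for both scans.
#' @param seeds integer vector of two seeds (baseline, post).
#' @return object of class `synthetic_scan_pair`: list with `baseline`,
#'   `post` (both `roi_timeseries`), `ground_truth`, `seeds`.
#' @export
simulate_scan_pair <- function(baseline_spec, planted = NULL,
                               T_baseline = 273L, T_post = 273L,
                               ar_coeff = 0, seeds = c(1L, 2L)) {
  stopifnot(inherits(baseline_spec, "covariance_spec"))
  post_spec <- baseline_spec
  if (!is.null(planted) && length(planted) > 0L) {
    for (ch in planted) post_spec <- do.call(apply_planted_change, c(list(post_spec), ch))
  }
  bl <- simulate_scan(baseline_spec, T_baseline, ar_coeff, seed = seeds[1L],
                      scan_id = "baseline")
  po <- simulate_scan(post_spec, T_post, ar_coeff, seed = seeds[2L],
                      scan_id = "post")
  structure(list(baseline = bl, post = po,
                 ground_truth = if (is.null(planted)) list() else planted,
                 seeds = seeds),
            class = "synthetic_scan_pair")
}

#' Default generator geometry
#'
#' 132 ROIs in 6 blocks of 22 with rho_in = 0.65 and rho_out = 0.1: at
#' T = 273, thresholding at |r| > 0.5 then yields dense within-block and
#' sparse between-block networks.
#'
#' @return a `covariance_spec`.
#' @export
default_covariance_spec <- function() {
  make_block_covariance(R = 132L, n_blocks = 6L, rho_in = 0.65, rho_out = 0.1)
}
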