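#' Single-subject connectome change analysis
#'
#' The package's central fitting function. Takes a subject's baseline and
#' post-treatment ROI time series, builds the binarized correlation network
#' of each scan (|r| > `threshold`), computes the six nodal graph metrics
#' (degree, clustering coefficient, betweenness centrality, nodal global
#' efficiency, local efficiency, average path length), tests each ROI's
#' pre/post difference per metric against a kernel-density resampling null
#' with BH FDR control, and runs the SD deviation screen.
#'
#' @param baseline,post [roi_timeseries()] objects, or paths to delimited
#'   time-series files readable by [read_roi_timeseries()]. Must share the
#'   ROI set and order; time-point counts may differ.
#' @param threshold correlation cutoff for the binary network (default
#'   0.5).
#' @param n_null_draws null draws per metric (default 100000).
#' @param q_threshold FDR level (default 0.1).
#' @param seed integer seed for the resampling nulls.
#' @param bandwidth_override optional fixed kernel bandwidth.
#' @param fdr_family `"per_metric"` (default) or `"pooled"`.
#' @param flag_threshold,stable_margin deviation-screen parameters; see
#'   [classify_trajectory()].
#' @return An object of class `netchange`: a list with components
#'   `correlation` (per-scan `correlation_matrix`), `network` (per-scan
#'   `binary_network`), `metrics` (per-scan metric tables), `results`
#'   (the per-ROI x metric test result table), `deviation` (the deviation
#'   report), `threshold_p` (analytic one-sided p of r = threshold at each
#'   scan's N), and `config` (the resolved settings).
#' @examples
#' spec <- make_block_covariance(R = 24, n_blocks = 3, rho_in = 0.55,
#'                               rho_out = 0.1)
#' pair <- simulate_scan_pair(spec,
#'   planted = list(list(target_rois = 1, mode = "detach", delta = 0.65)),
#'   T_baseline = 200, T_post = 200, seeds = c(11, 12))
#' fit <- netchange(pair$baseline, pair$post, n_null_draws = 2000, seed = 7)
#' summary(fit)
#' @export
netchange <- function(baseline, post, threshold = 0.5, n_null_draws = 100000L,
                      q_threshold = 0.1, seed = NULL,
                      bandwidth_override = NULL,
                      fdr_family = c("per_metric", "pooled"),
                      flag_threshold = 2, stable_margin = 0.5) {
  fdr_family <- match.arg(fdr_family)
  if (is.character(baseline)) baseline <- read_roi_timeseries(baseline)
  if (is.character(post)) post <- read_roi_timeseries(post)
  stopifnot(inherits(baseline, "roi_timeseries"), inherits(post, "roi_timeseries"))
  if (!identical(baseline$labels, post$labels)) {
    stop("baseline and post scans must share the ROI set and order")
  }
  scans <- list(baseline = baseline, post = post)
  corr <- lapply(scans, correlation_matrix)
  nets <- lapply(corr, threshold_network, tau = threshold)
  mets <- mapply(compute_metrics, nets, names(nets), SIMPLIFY = FALSE)
  results <- test_metric_changes(mets$baseline, mets$post, m = n_null_draws,
                                 q_threshold = q_threshold, seed = seed,
                                 bandwidth_override = bandwidth_override,
                                 fdr_family = fdr_family)
  deviation <- build_deviation_report(mets$baseline, mets$post,
                                      flag_threshold = flag_threshold,
                                      stable_margin = stable_margin)
  structure(list(
    correlation = corr, network = nets, metrics = mets,
    results = results, deviation = deviation,
    threshold_p = vapply(corr, function(cm)
      correlation_p_value(threshold, cm$n_samples), numeric(1L)),
    config = list(threshold = threshold, n_null_draws = n_null_draws,
                  q_threshold = q_threshold, seed = seed,
                  bandwidth_override = bandwidth_override,
                  fdr_family = fdr_family, flag_threshold = flag_threshold,
                  stable_margin = stable_margin)
  ), class = "netchange")
}

#' @export
print.netchange <- function(x, ...) {
  sig <- x$results[x$results$significant, , drop = FALSE]
  cat("Single-subject connectome change analysis\n")
  cat("  ROIs:", length(x$network$baseline$labels),
      " edges (baseline/post):",
      sum(x$network$baseline$adjacency) / 2, "/",
      sum(x$network$post$adjacency) / 2, "\n")
  cat("  threshold |r| >", x$config$threshold,
      sprintf(" (analytic p: %.3g baseline, %.3g post)\n",
              x$threshold_p["baseline"], x$threshold_p["post"]))
  cat("  significant ROI x metric rows at q <", x$config$q_threshold, ":",
      nrow(sig), "\n")
  invisible(x)
}

#' @export
summary.netchange <- function(object, ...) {
  res <- object$results
  sig <- res[res$significant, , drop = FALSE]
  per_metric <- table(factor(sig$metric, levels = metric_names()))
  dev <- object$deviation
  flagged <- unique(dev[dev$flagged & dev$scan == "baseline",
                        c("name", "metric", "trajectory")])
  out <- list(n_roi = length(object$network$baseline$labels),
              edges = c(baseline = sum(object$network$baseline$adjacency) / 2,
                        post = sum(object$network$post$adjacency) / 2),
              n_significant = nrow(sig),
              significant = sig,
              per_metric = per_metric,
              flagged_deviant = flagged,
              config = object$config)
  class(out) <- "summary.netchange"
  out
}

#' @export
print.summary.netchange <- function(x, ...) {
  cat("netchange summary:", x$n_roi, "ROIs;",
      x$edges["baseline"], "baseline /", x$edges["post"], "post edges\n")
  cat("Significant ROI x metric rows (q <", x$config$q_threshold, "):",
      x$n_significant, "\n")
  if (x$n_significant > 0L) {
    print(x$significant[, c("name", "metric", "baseline", "post", "diff",
                            "p", "q")], row.names = FALSE)
  }
  cat("Per metric:", paste(names(x$per_metric), as.integer(x$per_metric),
                           sep = "=", collapse = " "), "\n")
  if (nrow(x$flagged_deviant) > 0L) {
    cat("Deviant ROIs (|z| > 2 in a scan) and trajectories:\n")
    print(x$flagged_deviant, row.names = FALSE)
  }
  invisible(x)
}

#' Stem plots and bar plots for a fitted analysis
#'
#' @param x a `netchange` object.
#' @param metric which metric to plot (default `"GE"`).
#' @param type `"stem"`: per-scan stem plots of the metric across ROIs with
#'   horizontal reference lines at the cross-ROI mean plus/minus 1, 2 and 3
#'   SD; `"bars"`: pre/post bars for the significant ROIs of the metric.
#' @param ... passed to the underlying graphics calls.
#' @return invisibly, `x`.
#' @export
plot.netchange <- function(x, metric = "GE", type = c("stem", "bars"), ...) {
  type <- match.arg(type)
  stopifnot(metric %in% metric_names())
  if (type == "stem") {
    old <- graphics::par(mfrow = c(2, 1), mar = c(3.5, 4, 2, 1))
    on.exit(graphics::par(old))
    for (scan in c("baseline", "post")) {
      tab <- x$metrics[[scan]]
      v <- tab[[metric]]
      mu <- mean(v[is.finite(v)], na.rm = TRUE)
      s <- stats::sd(v[is.finite(v)], na.rm = TRUE)
      n_ok <- sum(is.finite(v))
      s <- s * sqrt((n_ok - 1) / n_ok)
      ylim <- range(c(v, mu + 3.2 * s, mu - 3.2 * s), finite = TRUE)
      plot(tab$index, v, type = "h", xlab = "", ylab = metric,
           main = paste(metric, "-", scan), ylim = ylim, ...)
      graphics::points(tab$index, v, pch = 16, cex = 0.5)
      for (k in 1:3) graphics::abline(h = mu + c(-k, k) * s, lty = k + 1,
                                      col = "grey40")
      graphics::abline(h = mu, col = "grey70")
    }
  } else {
    sig <- x$results[x$results$significant & x$results$metric == metric, ,
                     drop = FALSE]
    if (nrow(sig) == 0L) {
      message("no significant ROIs for ", metric, "; nothing to plot")
      return(invisible(x))
    }
    vals <- rbind(baseline = sig$baseline, post = sig$post)
    graphics::barplot(vals, beside = TRUE, names.arg = sig$name,
                      legend.text = TRUE, ylab = metric,
                      main = paste("Significant ROIs -", metric),
                      las = 2, ...)
  }
  invisible(x)
}
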