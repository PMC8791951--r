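## End-to-end orchestration: two time-series files in, result tables (and
## optionally figures) out, with a config echo sufficient to reproduce the
## run exactly.

#' Run the full change analysis from files to result tables
#'
#' Reads the two scans, fits [netchange()], and writes per-scan correlation
#' matrices, adjacency matrices and metric tables plus the cross-scan test
#' result table, deviation report and a JSON echo of the resolved
#' configuration into `output_dir`. With the same config and seed, the
#' output TSVs are byte-identical across runs.
#'
#' @param baseline,post paths to time-series files (or `roi_timeseries`
#'   objects).
#' @param output_dir directory for outputs (created if absent).
#' @param labels optional path to an ROI label file; names override any
#'   header labels.
#' @param threshold,n_null_draws,q_threshold,seed,bandwidth_override,fdr_family
#'   passed to [netchange()].
#' @param plots also write stem-plot PNGs per metric (default FALSE).
#' @param verbose print per-stage progress (default TRUE).
#' @return the fitted `netchange` object, invisibly; side effect: files in
#'   `output_dir`.
#' @export
run_change_analysis <- function(baseline, post, output_dir,
                                labels = NULL, threshold = 0.5,
                                n_null_draws = 100000L, q_threshold = 0.1,
                                seed = NULL, bandwidth_override = NULL,
                                fdr_family = "per_metric", plots = FALSE,
                                verbose = TRUE) {
  say <- function(...) if (verbose) message("[netchange] ", ...)
  t0 <- Sys.time()
  say("stage: read")
  if (is.character(baseline)) baseline <- read_roi_timeseries(baseline)
  if (is.character(post)) post <- read_roi_timeseries(post)
  if (!is.null(labels)) {
    lab <- read_roi_labels(labels)
    if (nrow(lab) != ncol(baseline$data)) {
      stop("label table has ", nrow(lab), " rows but scans have ",
           ncol(baseline$data), " ROIs")
    }
    baseline <- roi_timeseries(baseline$data, lab$name, baseline$scan_id)
    post <- roi_timeseries(post$data, lab$name, post$scan_id)
  }
  say("stage: analyze (T = ", nrow(baseline$data), "/", nrow(post$data),
      ", R = ", ncol(baseline$data), ")")
  fit <- netchange(baseline, post, threshold = threshold,
                   n_null_draws = n_null_draws, q_threshold = q_threshold,
                   seed = seed, bandwidth_override = bandwidth_override,
                   fdr_family = fdr_family)
  say("stage: write")
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  for (scan in c("baseline", "post")) {
    cm <- as.data.frame(fit$correlation[[scan]]$values)
    names(cm) <- fit$correlation[[scan]]$labels
    write_table(cbind(name = fit$correlation[[scan]]$labels, cm),
                file.path(output_dir, paste0("correlation_", scan, ".tsv")))
    adj <- as.data.frame(fit$network[[scan]]$adjacency)
    names(adj) <- fit$network[[scan]]$labels
    write_table(cbind(name = fit$network[[scan]]$labels, adj),
                file.path(output_dir, paste0("adjacency_", scan, ".tsv")))
    write_table(fit$metrics[[scan]],
                file.path(output_dir, paste0("metrics_", scan, ".tsv")))
  }
  write_table(as.data.frame(fit$results),
              file.path(output_dir, "test_results.tsv"))
  write_table(fit$deviation, file.path(output_dir, "deviation_report.tsv"))
  cfg <- fit$config
  cfg$n_timepoints <- c(baseline = nrow(baseline$data), post = nrow(post$data))
  cfg$threshold_p <- fit$threshold_p
  jsonlite::write_json(cfg, file.path(output_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  n_undef <- sum(!fit$metrics$baseline$apl_defined | !fit$metrics$post$apl_defined)
  if (n_undef > 0L) say(n_undef, " ROI(s) had undefined APL and were excluded from the APL test")
  if (plots) {
    say("stage: figures")
    render_figures(fit, output_dir)
  }
  say(sprintf("done in %.1fs", as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(fit)
}

#' Render stem plots and significant-ROI bar plots to PNG
#'
#' One stem-plot PNG per metric (baseline and post panels with mean and
#' plus/minus 1/2/3 SD reference lines) and, where a metric has significant
#' ROIs, a pre/post bar plot. Plotting failures are logged, never fatal.
#'
#' @param fit a `netchange` object.
#' @param output_dir directory for the PNGs.
#' @return invisibly, the vector of files written.
#' @export
render_figures <- function(fit, output_dir) {
  stopifnot(inherits(fit, "netchange"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  for (met in metric_names()) {
    f <- file.path(output_dir, paste0("stem_", met, ".png"))
    ok <- tryCatch({
      grDevices::png(f, width = 900, height = 700)
      plot(fit, metric = met, type = "stem")
      grDevices::dev.off()
      TRUE
    }, error = function(e) {
      message("stem plot for ", met, " failed: ", conditionMessage(e))
      try(grDevices::dev.off(), silent = TRUE)
      FALSE
    })
    if (ok) written <- c(written, f)
    if (any(fit$results$significant & fit$results$metric == met)) {
      f2 <- file.path(output_dir, paste0("bars_", met, ".png"))
      ok2 <- tryCatch({
        grDevices::png(f2, width = 700, height = 500)
        plot(fit, metric = met, type = "bars")
        grDevices::dev.off()
        TRUE
      }, error = function(e) {
        message("bar plot for ", met, " failed: ", conditionMessage(e))
        try(grDevices::dev.off(), silent = TRUE)
        FALSE
      })
      if (ok2) written <- c(written, f2)
    } else {
      message("no significant ROIs for ", met, "; bar plot skipped")
    }
  }
  # node-edge depiction of each scan, significant ROIs highlighted
  sig_rois <- unique(fit$results$name[fit$results$significant])
  for (scan in c("baseline", "post")) {
    f3 <- file.path(output_dir, paste0("network_", scan, ".png"))
    ok3 <- tryCatch({
      g <- igraph::graph_from_adjacency_matrix(fit$network[[scan]]$adjacency,
                                               mode = "undirected",
                                               diag = FALSE)
      grDevices::png(f3, width = 800, height = 800)
      plot(g, vertex.size = 4, vertex.label = NA,
           vertex.color = ifelse(fit$network[[scan]]$labels %in% sig_rois,
                                 "red", "grey70"),
           layout = igraph::layout_with_fr(g, niter = 100),
           main = paste("Thresholded network -", scan,
                        "(significant ROIs in red)"))
      grDevices::dev.off()
      TRUE
    }, error = function(e) {
      message("network depiction for ", scan, " failed: ",
              conditionMessage(e))
      try(grDevices::dev.off(), silent = TRUE)
      FALSE
    })
    if (ok3) written <- c(written, f3)
  }
  invisible(written)
}

#' Write a synthetic scan pair to disk
#'
#' Writes the baseline and post time series as headered TSVs plus a JSON
#' ground-truth sidecar, for driving the pipeline from files.
#'
#' @param pair a `synthetic_scan_pair`.
#' @param output_dir destination directory.
#' @return invisibly, named vector of the three file paths.
#' @export
write_scan_pair <- function(pair, output_dir) {
  stopifnot(inherits(pair, "synthetic_scan_pair"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(baseline = file.path(output_dir, "baseline.tsv"),
             post = file.path(output_dir, "post.tsv"),
             truth = file.path(output_dir, "ground_truth.json"))
  for (scan in c("baseline", "post")) {
    df <- as.data.frame(pair[[scan]]$data)
    names(df) <- pair[[scan]]$labels
    write_table(df, paths[[scan]])
  }
  jsonlite::write_json(list(planted = pair$ground_truth, seeds = pair$seeds),
                       paths[["truth"]], auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(paths)
}
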