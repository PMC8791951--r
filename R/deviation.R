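## Exploratory deviation screen: which ROIs sit far from the cross-ROI
## mean of a metric (in SD units), and does a flagged ROI move toward the
## mean (normalize) or away from it (diverge) after treatment?

#' Cross-ROI z-scores of each metric within one scan
#'
#' `z_i = (x_i - mean) / SD` using the population SD (divide by n) of the
#' metric across ROIs within the scan; undefined entries are excluded from
#' the mean/SD and returned as NA.
#'
#' @param table metric table from [compute_metrics()].
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return data.frame: index, name, scan_id, one `z_<metric>` column per
#'   metric, and a `band_<metric>` column with the SD band (0: within 1 SD,
#'   1: 1-2 SD, 2: 2-3 SD, 3: beyond 3 SD).
#' @export
zscore_by_scan <- function(table, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  out <- data.frame(index = table$index, name = table$name,
                    scan_id = table$scan_id, stringsAsFactors = FALSE)
  for (met in metric_names()) {
    x <- table[[met]]
    ok <- is.finite(x)
    if (met == "APL") ok <- ok & table$apl_defined
    if (sum(ok) < 3L) stop("need at least 3 defined values for metric ", met)
    mu <- mean(x[ok])
    s <- stats::sd(x[ok])
    if (sd_type == "population") s <- s * sqrt((sum(ok) - 1) / sum(ok))
    if (s == 0) stop("zero cross-ROI SD for metric ", met,
                     ": z-scores undefined")
    z <- rep(NA_real_, length(x))
    z[ok] <- (x[ok] - mu) / s
    out[[paste0("z_", met)]] <- z
    out[[paste0("band_", met)]] <- ifelse(is.na(z), NA_integer_,
                                          pmin(floor(abs(z)), 3L))
  }
  out
}

#' Classify a flagged ROI's pre/post trajectory
#'
#' An ROI flagged as deviant (max |z| over the two scans above
#' `flag_threshold`) is labelled `normalized` if its |z| shrank by at least
#' `stable_margin` SD, `diverged` if it grew by at least that much, and
#' `stable` otherwise. The margin makes the visual notion of "converged to
#' the mean" explicit and testable.
#'
#' @param z_pre,z_post z-scores of the ROI in the baseline and post scans
#'   (vectorized).
#' @param flag_threshold |z| above which an ROI counts as deviant
#'   (default 2).
#' @param stable_margin minimum |z| change, in SD units, to call a
#'   direction (default 0.5).
#' @return character vector of labels.
#' @export
classify_trajectory <- function(z_pre, z_post, flag_threshold = 2,
                                stable_margin = 0.5) {
  flagged <- pmax(abs(z_pre), abs(z_post)) > flag_threshold
  if (any(!flagged, na.rm = TRUE)) {
    stop("trajectory undefined for unflagged ROI(s): max |z| <= ",
         flag_threshold)
  }
  ifelse(abs(z_post) <= abs(z_pre) - stable_margin, "normalized",
         ifelse(abs(z_post) >= abs(z_pre) + stable_margin, "diverged",
                "stable"))
}

#' Build the full deviation report for a scan pair
#'
#' One row per ROI x metric x scan with the value, cross-ROI mean and SD,
#' z-score and SD band; flagged ROIs (|z| > `flag_threshold` in at least
#' one scan) additionally carry a trajectory label.
#'
#' @param baseline,post metric tables from [compute_metrics()] with
#'   matching ROI sets.
#' @param flag_threshold,stable_margin see [classify_trajectory()].
#' @param sd_type see [zscore_by_scan()].
#' @return data.frame with columns index, name, metric, scan (baseline /
#'   post), value, cross_mean, cross_sd, z, band, flagged, trajectory (NA
#'   for unflagged rows).
#' @export
build_deviation_report <- function(baseline, post, flag_threshold = 2,
                                   stable_margin = 0.5,
                                   sd_type = "population") {
  if (!identical(baseline$name, post$name)) {
    stop("baseline and post tables must share ROI set and order")
  }
  tabs <- list(baseline = baseline, post = post)
  # like zscore_by_scan, but a zero-SD metric is skipped (all-NA z) rather
  # than an error: the screen is descriptive, and a metric constant across
  # ROIs simply has nothing to flag
  zs <- list()
  rows <- list()
  for (scan in names(tabs)) {
    tab <- tabs[[scan]]
    z <- data.frame(index = tab$index)
    for (met in metric_names()) {
      x <- tab[[met]]
      ok <- is.finite(x)
      if (met == "APL") ok <- ok & tab$apl_defined
      mu <- mean(x[ok])
      s <- stats::sd(x[ok])
      if (sd_type == "population") s <- s * sqrt((sum(ok) - 1) / sum(ok))
      zz <- rep(NA_real_, length(x))
      if (sum(ok) >= 3L && s > 0) {
        zz[ok] <- (x[ok] - mu) / s
      } else {
        message("deviation screen: metric ", met, " in ", scan,
                " scan has no cross-ROI spread; skipped")
        s <- NA_real_
      }
      z[[paste0("z_", met)]] <- zz
      rows[[paste(scan, met)]] <- data.frame(
        index = tab$index, name = tab$name, metric = met, scan = scan,
        value = x, cross_mean = mu, cross_sd = s,
        z = zz, band = ifelse(is.na(zz), NA_integer_,
                              pmin(floor(abs(zz)), 3L)),
        stringsAsFactors = FALSE, row.names = NULL)
    }
    zs[[scan]] <- z
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  # trajectory per ROI x metric
  out$flagged <- FALSE
  out$trajectory <- NA_character_
  zb <- zs$baseline
  zp <- zs$post
  for (met in metric_names()) {
    z1 <- zb[[paste0("z_", met)]]
    z2 <- zp[[paste0("z_", met)]]
    fl <- !is.na(z1) & !is.na(z2) & pmax(abs(z1), abs(z2)) > flag_threshold
    traj <- rep(NA_character_, length(fl))
    if (any(fl)) {
      traj[fl] <- classify_trajectory(z1[fl], z2[fl], flag_threshold,
                                      stable_margin)
    }
    sel <- out$metric == met
    out$flagged[sel] <- fl[match(out$index[sel], zb$index)]
    out$trajectory[sel] <- traj[match(out$index[sel], zb$index)]
  }
  out
}
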