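## Single-subject nonparametric change test.
##
## The null model asks: if a metric's value at a random ROI were simply
## re-drawn from the subject's own baseline cross-ROI distribution, how
## large a pre/post difference would arise by chance? A Gaussian kernel
## density is fitted to the baseline values of each metric, m pairs of
## independent draws are taken, and their differences form the null against
## which each ROI's observed (post - baseline) difference is ranked.

#' Fit a Gaussian kernel density to per-ROI metric values
#'
#' Bandwidth is the normal-reference (Silverman) rule
#' `h = sd(x) * (4 / (3 n))^(1/5)`, approximately `1.06 * sd(x) * n^(-1/5)`.
#' Sampling from the fitted model picks a support value uniformly at random
#' and adds Gaussian noise of scale h.
#'
#' @param values numeric vector of at least 8 finite values, not all
#'   identical.
#' @param bandwidth optional override of the Silverman bandwidth (> 0).
#' @return An object of class `kde_model`: list with `support_values`,
#'   `bandwidth`, `kernel = "gaussian"`.
#' @export
fit_kernel_density <- function(values, bandwidth = NULL) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 8L) stop("need at least 8 finite values to fit a kernel density, got ", n)
  s <- stats::sd(values)
  if (s == 0) stop("all values identical: kernel bandwidth would be zero")
  if (is.null(bandwidth)) bandwidth <- s * (4 / (3 * n))^(1 / 5)
  if (!(is.numeric(bandwidth) && bandwidth > 0)) stop("bandwidth must be > 0")
  structure(list(support_values = values, bandwidth = bandwidth,
                 kernel = "gaussian"),
            class = "kde_model")
}

#' Evaluate the fitted kernel density
#'
#' @param model a `kde_model`.
#' @param x points at which to evaluate.
#' @return density values (mean of Gaussian kernels centered at the support
#'   values).
#' @export
kde_density <- function(model, x) {
  stopifnot(inherits(model, "kde_model"))
  vapply(x, function(xi) {
    mean(stats::dnorm(xi, mean = model$support_values, sd = model$bandwidth))
  }, numeric(1L))
}

#' Draw random samples from a fitted kernel density
#'
#' @param model a `kde_model`.
#' @param n number of draws.
#' @return numeric vector of n samples.
#' @export
kde_sample <- function(model, n) {
  stopifnot(inherits(model, "kde_model"))
  centers <- sample(model$support_values, n, replace = TRUE)
  centers + stats::rnorm(n, sd = model$bandwidth)
}

#' Generate the null distribution of metric differences
#'
#' Draws two independent samples from the fitted baseline density and takes
#' their difference, m times. The resulting distribution is symmetric about
#' zero in expectation and represents the size of pre/post difference
#' obtainable by chance alone.
#'
#' @param model a `kde_model` fitted to baseline values.
#' @param m number of null draws (default 100000, minimum 1000).
#' @param seed integer seed; the null is fully reproducible given it.
#' @param metric_name recorded for bookkeeping.
#' @return An object of class `null_distribution`: list with `differences`
#'   (length m), `m`, `seed`, `metric_name`.
#' @export
generate_null_differences <- function(model, m = 100000L, seed = NULL,
                                      metric_name = NA_character_) {
  stopifnot(inherits(model, "kde_model"))
  if (m < 1000L) stop("need m >= 1000 null draws")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  d <- kde_sample(model, m) - kde_sample(model, m)
  structure(list(differences = d, m = as.integer(m), seed = seed,
                 metric_name = metric_name),
            class = "null_distribution")
}

#' Empirical two-sided p-value against a resampling null
#'
#' `p = #(|null| >= |observed|) / m`. Because a plain fraction can be zero
#' at finite m, a raw count of 0 is floored at 1/m and flagged: BH
#' correction requires p > 0 and an empirical tail beyond all m draws is
#' only known to be smaller than 1/m.
#'
#' @param observed_diff observed metric difference (post - baseline);
#'   vectorized.
#' @param null a `null_distribution`.
#' @return data.frame with columns `p` and `p_floored`.
#' @export
empirical_p_value <- function(observed_diff, null) {
  stopifnot(inherits(null, "null_distribution"))
  absnull <- abs(null$differences)
  m <- null$m
  cnt <- vapply(abs(observed_diff), function(a) sum(absnull >= a), numeric(1L))
  floored <- cnt == 0
  p <- pmax(cnt, 1) / m
  data.frame(p = p, p_floored = floored)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values via `stats::p.adjust(method = "BH")`, with a
#' significance flag at `q < q_threshold`.
#'
#' @param p_values vector of p-values in (0, 1].
#' @param q_threshold FDR level (default 0.1).
#' @return data.frame with columns `q` and `significant`.
#' @export
bh_fdr <- function(p_values, q_threshold = 0.1) {
  if (length(p_values) == 0L) stop("empty p-value vector")
  if (any(!is.finite(p_values)) || any(p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  q <- stats::p.adjust(p_values, method = "BH")
  data.frame(q = q, significant = q < q_threshold)
}

#' Test per-ROI metric changes between two scans
#'
#' For each of the six nodal metrics independently: fit the kernel density
#' to the BASELINE values across ROIs, generate one null of `m` differences,
#' rank each ROI's observed (post - baseline) difference in it two-sidedly,
#' and apply BH FDR across the ROIs of that metric. ROIs with an undefined
#' entry (APL of an isolated node) are dropped from that metric's family
#' with a message.
#'
#' @param baseline,post metric tables from [compute_metrics()], sharing ROI
#'   set and order.
#' @param m null draws per metric (default 100000).
#' @param q_threshold FDR level (default 0.1).
#' @param seed integer seed; metric k uses `seed + k - 1` so the six nulls
#'   are independent yet reproducible.
#' @param bandwidth_override optional fixed kernel bandwidth for all
#'   metrics.
#' @param fdr_family `"per_metric"` (default): BH within each metric's R
#'   ROIs; `"pooled"`: one family across all 6 x R tests.
#' @param fresh_null_per_roi if TRUE, draw a separate null for every ROI
#'   (statistically identical, much slower; for fidelity checks).
#' @return data.frame of class `test_result_table`: one row per ROI x
#'   metric with columns index, name, metric, baseline, post, diff, p,
#'   p_floored, q, significant; attributes `q_threshold`, `m`, `seed`.
#' @export
test_metric_changes <- function(baseline, post, m = 100000L, q_threshold = 0.1,
                                seed = NULL, bandwidth_override = NULL,
                                fdr_family = c("per_metric", "pooled"),
                                fresh_null_per_roi = FALSE) {
  fdr_family <- match.arg(fdr_family)
  if (!identical(baseline$name, post$name)) {
    stop("baseline and post tables must share ROI set and order")
  }
  rows <- list()
  for (k in seq_along(metric_names())) {
    met <- metric_names()[k]
    b <- baseline[[met]]
    a <- post[[met]]
    keep <- is.finite(b) & is.finite(a)
    if (met == "APL") {
      keep <- keep & baseline$apl_defined & post$apl_defined
    }
    if (any(!keep)) {
      message(sum(!keep), " ROI(s) dropped from the ", met,
              " test (undefined values): ",
              paste(utils::head(baseline$name[!keep], 5L), collapse = ", "))
    }
    if (sum(keep) < 8L || stats::sd(b[keep]) == 0) {
      message("metric ", met, " skipped: baseline values ",
              if (sum(keep) < 8L) "too few" else "all identical",
              " (no cross-ROI spread to fit a null)")
      next
    }
    model <- fit_kernel_density(b[keep], bandwidth = bandwidth_override)
    met_seed <- if (is.null(seed)) NULL else seed + k - 1L
    diffs <- a[keep] - b[keep]
    if (fresh_null_per_roi) {
      pres <- do.call(rbind, lapply(seq_along(diffs), function(i) {
        s_i <- if (is.null(met_seed)) NULL else met_seed + 1000L * i
        nd <- generate_null_differences(model, m, seed = s_i, metric_name = met)
        empirical_p_value(diffs[i], nd)
      }))
    } else {
      nd <- generate_null_differences(model, m, seed = met_seed,
                                      metric_name = met)
      pres <- empirical_p_value(diffs, nd)
    }
    rows[[met]] <- data.frame(
      index = baseline$index[keep], name = baseline$name[keep], metric = met,
      baseline = b[keep], post = a[keep], diff = diffs,
      p = pres$p, p_floored = pres$p_floored,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  if (length(rows) == 0L) {
    stop("no metric has enough cross-ROI spread at baseline to fit a null; ",
         "the thresholded network is too regular for the subject-level test")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (fdr_family == "per_metric") {
    out$q <- NA_real_
    out$significant <- NA
    for (met in unique(out$metric)) {
      sel <- out$metric == met
      adj <- bh_fdr(out$p[sel], q_threshold)
      out$q[sel] <- adj$q
      out$significant[sel] <- adj$significant
    }
  } else {
    adj <- bh_fdr(out$p, q_threshold)
    out$q <- adj$q
    out$significant <- adj$significant
  }
  attr(out, "q_threshold") <- q_threshold
  attr(out, "m") <- as.integer(m)
  attr(out, "seed") <- seed
  class(out) <- c("test_result_table", "data.frame")
  out
}
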