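#' ROI time-series container
#'
#' Construct and validate a single scan's denoised, ROI-averaged signal
#' matrix. The canonical orientation is time by ROI: one row per acquired
#' volume, one column per region.
#'
#' @param data numeric matrix, T rows (time points) by R columns (ROIs).
#' @param labels character vector of R unique ROI names. Defaults to
#'   `"ROI_0001"`-style names.
#' @param scan_id free-text scan identifier.
#' @param t_repeat optional repetition time in seconds (metadata only; not
#'   used by any computation).
#'
#' @return An object of class `roi_timeseries`: a list with elements
#'   `data`, `labels`, `scan_id`, `t_repeat`.
#'
#' @details Validation rejects anything the downstream correlation step
#'   cannot handle: fewer than 3 time points or 2 ROIs, non-finite values
#'   (there is no imputation step in this pipeline), and duplicate labels.
#' @export
roi_timeseries <- function(data, labels = NULL, scan_id = "scan", t_repeat = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("time-series data must be numeric")
  if (nrow(data) < 3L) stop("need at least 3 time points (T >= 3), got ", nrow(data))
  if (ncol(data) < 2L) stop("need at least 2 ROIs (R >= 2), got ", ncol(data))
  bad <- which(!is.finite(data), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    show <- utils::head(bad, 5L)
    stop("non-finite values at (row, column): ",
         paste(sprintf("(%d,%d)", show[, 1L], show[, 2L]), collapse = " "),
         if (nrow(bad) > 5L) sprintf(" and %d more", nrow(bad) - 5L) else "")
  }
  if (is.null(labels)) {
    labels <- colnames(data)
    if (is.null(labels)) labels <- sprintf("ROI_%04d", seq_len(ncol(data)))
  }
  labels <- trimws(as.character(labels))
  if (length(labels) != ncol(data)) {
    stop("label count (", length(labels), ") != ROI count (", ncol(data), ")")
  }
  if (anyDuplicated(labels)) {
    stop("duplicate ROI labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  colnames(data) <- labels
  rownames(data) <- NULL
  structure(list(data = data, labels = labels,
                 scan_id = as.character(scan_id)[1L], t_repeat = t_repeat),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat("ROI time series '", x$scan_id, "': ",
      nrow(x$data), " time points x ", ncol(x$data), " ROIs\n", sep = "")
  invisible(x)
}

#' Read ROI time series from delimited text
#'
#' Reads a rectangular numeric matrix from a TSV/CSV file, with an optional
#' single header row of ROI labels, and returns a validated
#' [roi_timeseries()] in the canonical time-by-ROI orientation regardless of
#' how the file is laid out.
#'
#' @param path path to the delimited file.
#' @param orientation `"time_by_roi"` (default; rows are volumes) or
#'   `"roi_by_time"` (rows are ROIs; the matrix is transposed on read).
#' @param delimiter field separator; `""` (default) splits on any whitespace,
#'   otherwise e.g. `","` or `"\t"`.
#' @param scan_id scan identifier attached to the result; defaults to the
#'   file name without extension.
#' @return A validated `roi_timeseries`.
#' @export
read_roi_timeseries <- function(path, orientation = c("time_by_roi", "roi_by_time"),
                                delimiter = "", scan_id = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty file: ", path)
  split1 <- function(s) {
    if (identical(delimiter, "")) strsplit(trimws(s), "[ \t,;]+")[[1L]]
    else strsplit(s, delimiter, fixed = TRUE)[[1L]]
  }
  cells <- lapply(lines, split1)
  widths <- lengths(cells)
  if (length(unique(widths)) != 1L) {
    stop("ragged rows: widths ", paste(unique(widths), collapse = ", "),
         " (first offending line ", which(widths != widths[1L])[1L], ")")
  }
  first <- suppressWarnings(as.numeric(cells[[1L]]))
  has_header <- anyNA(first)
  labels <- NULL
  if (has_header) {
    labels <- trimws(cells[[1L]])
    cells <- cells[-1L]
    if (length(cells) == 0L) stop("file has a header but no data rows: ", path)
  }
  mat <- matrix(NA_real_, nrow = length(cells), ncol = widths[1L])
  for (i in seq_along(cells)) {
    v <- suppressWarnings(as.numeric(cells[[i]]))
    bad <- which(is.na(v) & !(cells[[i]] %in% c("NA", "NaN")))
    if (length(bad) > 0L) {
      stop("non-numeric cell at data row ", i, ", column ", bad[1L],
           ": '", cells[[i]][bad[1L]], "'")
    }
    mat[i, ] <- v
  }
  if (orientation == "roi_by_time") mat <- t(mat)
  if (is.null(scan_id)) scan_id <- tools::file_path_sans_ext(basename(path))
  roi_timeseries(mat, labels = labels, scan_id = scan_id)
}

#' Read an ROI label table
#'
#' Reads a delimited table with at least `index` and `name` columns
#' (optionally `group`). Indices must be the gap-free sequence 0..R-1 and
#' names must be unique after whitespace trimming.
#'
#' @param path path to the label file (TSV or CSV, header optional if the
#'   columns are in index, name, group order).
#' @return data.frame with columns `index` (0-based integer), `name`, and
#'   `group` (NA where absent).
#' @export
read_roi_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, sep = "", header = FALSE,
                           stringsAsFactors = FALSE, fill = FALSE,
                           colClasses = "character")
  if (ncol(tab) == 1L) {
    tab <- utils::read.table(path, sep = ",", header = FALSE,
                             stringsAsFactors = FALSE,
                             colClasses = "character")
  }
  # drop a header row if the first index cell is not numeric
  if (is.na(suppressWarnings(as.numeric(tab[1L, 1L])))) tab <- tab[-1L, , drop = FALSE]
  if (ncol(tab) < 2L) stop("label table needs at least index and name columns")
  idx <- suppressWarnings(as.integer(tab[[1L]]))
  if (anyNA(idx)) stop("non-integer ROI index at row ", which(is.na(idx))[1L])
  name <- trimws(tab[[2L]])
  group <- if (ncol(tab) >= 3L) trimws(tab[[3L]]) else rep(NA_character_, length(name))
  out <- data.frame(index = idx, name = name, group = group,
                    stringsAsFactors = FALSE)
  out <- out[order(out$index), , drop = FALSE]
  rownames(out) <- NULL
  if (!identical(out$index, 0:(nrow(out) - 1L))) {
    stop("ROI indices must be the gap-free sequence 0..R-1")
  }
  if (anyDuplicated(out$name)) {
    stop("duplicate ROI names: ",
         paste(unique(out$name[duplicated(out$name)]), collapse = ", "))
  }
  out
}

#' Write a tabular result to TSV at full precision
#'
#' Writes any of the pipeline's tabular outputs (metric tables, test result
#' tables, deviation reports) as tab-delimited text with a header row.
#' Numeric columns are formatted at 17 significant digits so that a
#' write/read round trip reproduces the values bit for bit.
#'
#' @param rows non-empty data.frame.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_table <- function(rows, path) {
  if (!is.data.frame(rows) || nrow(rows) == 0L) stop("refusing to write an empty table")
  out <- rows
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) stop("cannot write ", path, ": ", conditionMessage(e)))
  invisible(path)
}

#' Read back a table written by [write_table()]
#'
#' @param path path to a TSV written by [write_table()].
#' @return data.frame with numeric columns restored.
#' @export
read_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}
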