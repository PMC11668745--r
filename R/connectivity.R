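#' ROI connectivity matrix
#'
#' @param values symmetric `n_rois x n_rois` numeric matrix.
#' @param kind `"pearson"` or `"fisher_z"`.
#' @param roi_names ROI labels in row/column order.
#' @return object of class `conn_matrix`.
#' @export
conn_matrix <- function(values, kind = c("pearson", "fisher_z"),
                        roi_names = rownames(values)) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  stopifnot(nrow(values) == ncol(values), length(roi_names) == nrow(values))
  if (max(abs(values - t(values))) > 1e-10)
    stop("connectivity matrix must be symmetric")
  if (kind == "pearson" &&
      (min(values) < -1 - 1e-12 || max(values) > 1 + 1e-12))
    stop("pearson entries must lie in [-1, 1]")
  dimnames(values) <- list(roi_names, roi_names)
  structure(list(values = values, kind = kind, roi_labels = roi_names),
            class = "conn_matrix")
}

#' @export
print.conn_matrix <- function(x, ...) {
  cat(sprintf("<conn_matrix> %s, %d x %d ROIs\n",
              x$kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Pearson correlation matrix of one subject's ROI time courses
#'
#' Entry `(j, k)` is the Pearson correlation of ROI rows `j` and `k`;
#' symmetric with unit diagonal. Constant rows have no defined correlation
#' and are rejected by name.
#'
#' @param ts a [roi_ts()].
#' @return a [conn_matrix()] of kind `"pearson"`.
#' @examples
#' ts <- roi_ts("s1", "g", rbind(a = c(1, 2, 3), b = c(3, 2, 1)))
#' pearson_matrix(ts)$values
#' @export
pearson_matrix <- function(ts) {
  stopifnot(inherits(ts, "roi_ts"))
  if (length(ts$constant_rois))
    stop("zero-variance ROI row(s): ",
         paste(ts$constant_rois, collapse = ", "))
  r <- stats::cor(t(ts$signals))
  # cor() is symmetric up to rounding; make it exact and pin the diagonal
  r <- (r + t(r)) / 2
  diag(r) <- 1
  r[r > 1] <- 1; r[r < -1] <- -1
  conn_matrix(r, "pearson", ts$roi_labels)
}

#' Fisher z-transform of a Pearson connectivity matrix
#'
#' Applies `atanh` entry-wise to the off-diagonal correlations. `atanh`
#' diverges at |r| = 1, so correlations are clipped to `1 - eps` in
#' magnitude first (with a warning when clipping fires off-diagonal); the
#' diagonal is set to `atanh(1 - eps)`, the transform's finite maximum,
#' keeping the matrix usable as classifier input.
#'
#' @param corr a [conn_matrix()] of kind `"pearson"`.
#' @param eps clipping margin (default `1e-7`).
#' @return a [conn_matrix()] of kind `"fisher_z"`.
#' @export
fisher_z <- function(corr, eps = 1e-7) {
  stopifnot(inherits(corr, "conn_matrix"))
  if (corr$kind != "pearson")
    stop("fisher_z expects a pearson matrix, got ", corr$kind)
  r <- corr$values
  off <- r; diag(off) <- 0
  if (max(abs(off)) >= 1)
    warning("off-diagonal |r| = 1 clipped to ", 1 - eps)
  r[r > 1 - eps] <- 1 - eps
  r[r < -(1 - eps)] <- -(1 - eps)
  z <- atanh(r)
  diag(z) <- atanh(1 - eps)
  conn_matrix(z, "fisher_z", corr$roi_labels)
}

#' Write / read a connectivity or attention matrix as labelled CSV
#'
#' Square matrices travel as CSV with the ROI labels as header and first
#' column, so every artifact on disk is re-readable by the stage that
#' consumes it.
#'
#' @param m numeric matrix with dimnames.
#' @param path CSV path.
#' @return `path` (write) or the matrix (read), invisibly for the writer.
#' @export
write_matrix_csv <- function(m, path) {
  df <- data.frame(roi = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}
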