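#' Coefficient of variation of one ROI's attention row
#'
#' Dispersion of how ROI `roi_index` distributes attention over all ROIs
#' within one subject: population standard deviation of the row divided by
#' its mean. Softmax rows have positive mean, so the ratio is always
#' defined; it is invariant to positive rescaling of the row. Column-wise
#' CV and the sample (n-1) standard deviation are available as options.
#'
#' @param attnM an [attn_matrix()].
#' @param roi_index row (or column) index or ROI label.
#' @param margin `"row"` (default) or `"column"`.
#' @param sd_type `"population"` (default, divisor n) or `"sample"`.
#' @return nonnegative scalar.
#' @export
roi_cv <- function(attnM, roi_index, margin = c("row", "column"),
                   sd_type = c("population", "sample")) {
  margin <- match.arg(margin); sd_type <- match.arg(sd_type)
  stopifnot(inherits(attnM, "attn_matrix"))
  if (is.character(roi_index))
    roi_index <- match(roi_index, attnM$roi_labels)
  if (is.na(roi_index) || roi_index < 1 || roi_index > nrow(attnM$values))
    stop("invalid ROI index")
  v <- if (margin == "row") attnM$values[roi_index, ]
       else attnM$values[, roi_index]
  m <- mean(v)
  if (m == 0) stop("zero-mean attention row; cannot form a CV")
  n <- length(v)
  s <- stats::sd(v)
  if (sd_type == "population") s <- s * sqrt((n - 1) / n)
  s / m
}

#' Group representative matrix of coefficients of variation
#'
#' Stacks one row per subject of a group; entry `(i, j)` is the CV of
#' subject `i`'s attention row for ROI `j`. This subjects-by-ROI matrix is
#' the item-response input of the latent space model.
#'
#' @param attn_matrices list of [attn_matrix()] objects from one group,
#'   sharing ROI labels and comparison.
#' @param margin,sd_type passed to [roi_cv()].
#' @return object of class `group_rep_matrix`: list with `values`
#'   (`N_g x n_rois`), `subject_ids`, `roi_labels`, `group`, `comparison`.
#' @export
build_group_matrix <- function(attn_matrices, margin = "row",
                               sd_type = "population") {
  stopifnot(length(attn_matrices) >= 1L,
            all(vapply(attn_matrices, inherits, logical(1), "attn_matrix")))
  labs <- attn_matrices[[1]]$roi_labels
  ok <- vapply(attn_matrices, function(a) identical(a$roi_labels, labs),
               logical(1))
  if (!all(ok)) stop("heterogeneous ROI sets across attention matrices")
  vals <- t(vapply(attn_matrices, function(a)
    vapply(seq_along(labs), function(j) roi_cv(a, j, margin, sd_type),
           numeric(1)),
    numeric(length(labs))))
  rownames(vals) <- vapply(attn_matrices, `[[`, character(1), "subject_id")
  colnames(vals) <- labs
  structure(list(values = vals,
                 subject_ids = rownames(vals), roi_labels = labs,
                 group = attn_matrices[[1]]$group,
                 comparison = attn_matrices[[1]]$comparison),
            class = "group_rep_matrix")
}

#' @export
print.group_rep_matrix <- function(x, ...) {
  cat(sprintf("<group_rep_matrix> group %s: %d subjects x %d ROIs\n",
              x$group, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Select the top-quartile ROIs of a group
#'
#' Ranks ROIs by two per-ROI statistics — mean CV (averaged over the
#' group's subjects) and mean attention — and returns the
#' `floor(0.25 * n_rois)` best. Because every attention row sums to one,
#' an ROI's row mean is identically `1/n_rois`; the informative mean is
#' over the ROI's column (attention the ROI receives from all ROIs),
#' which is the default `mean_margin`.
#' The default combination is the unweighted rank sum of the two
#' statistics; `mode = "intersection"` instead intersects the two
#' top-quartile sets (which may return fewer ROIs). Ties are broken by
#' higher mean attention, then alphabetically, so selection is
#' deterministic.
#'
#' @param group_matrix a [build_group_matrix()] result.
#' @param attn_matrices the same group's attention matrices (mean
#'   attention source).
#' @param mode `"rank_sum"` (default) or `"intersection"`.
#' @param mean_margin `"column"` (default; attention received) or `"row"`
#'   for the mean-attention statistic.
#' @return object of class `top_roi_list`: data.frame `ranking` with
#'   columns `rank`, `roi`, `mean_cv`, `mean_attention`, plus `group`,
#'   `mode`, `n_rois`.
#' @export
top_quartile_rois <- function(group_matrix, attn_matrices,
                              mode = c("rank_sum", "intersection"),
                              mean_margin = c("column", "row")) {
  mode <- match.arg(mode)
  mean_margin <- match.arg(mean_margin)
  stopifnot(inherits(group_matrix, "group_rep_matrix"))
  labs <- group_matrix$roi_labels
  R <- length(labs)
  if (R < 4L) stop("top-quartile selection undefined for fewer than 4 ROIs")
  ok <- vapply(attn_matrices, function(a) identical(a$roi_labels, labs),
               logical(1))
  if (!all(ok)) stop("attention matrices do not match the group matrix ROIs")
  mean_cv <- colMeans(group_matrix$values)
  per_roi <- if (mean_margin == "column") function(a) colMeans(a$values)
             else function(a) rowMeans(a$values)
  mean_attn <- rowMeans(vapply(attn_matrices, per_roi, numeric(R)))
  k <- floor(0.25 * R)
  # rank 1 = best; average ranks for exact ties keep the sum well-defined
  r_cv <- rank(-mean_cv, ties.method = "average")
  r_at <- rank(-mean_attn, ties.method = "average")
  score <- r_cv + r_at
  ord <- order(score, -mean_attn, labs)
  sel <- switch(mode,
    rank_sum = ord[seq_len(k)],
    intersection = {
      q_cv <- which(r_cv <= k); q_at <- which(r_at <= k)
      both <- intersect(q_cv, q_at)
      both[order(score[both], -mean_attn[both], labs[both])]
    })
  ranking <- data.frame(rank = seq_along(sel), roi = labs[sel],
                        mean_cv = mean_cv[sel], mean_attention = mean_attn[sel],
                        row.names = NULL)
  structure(list(ranking = ranking, group = group_matrix$group,
                 comparison = group_matrix$comparison,
                 mode = mode, n_rois = R),
            class = "top_roi_list")
}

#' @export
print.top_roi_list <- function(x, ...) {
  cat(sprintf("<top_roi_list> group %s (%s): %d of %d ROIs\n",
              x$group, x$mode, nrow(x$ranking), x$n_rois))
  print(utils::head(x$ranking, 10), row.names = FALSE)
  if (nrow(x$ranking) > 10) cat("  ...\n")
  invisible(x)
}

#' Write group-representation artifacts
#'
#' @param group_matrix a [build_group_matrix()] result.
#' @param top a [top_quartile_rois()] result.
#' @param matrix_path,top_path CSV output paths (`NULL` to skip).
#' @return invisibly `NULL`.
#' @export
write_group_rep <- function(group_matrix = NULL, top = NULL,
                            matrix_path = NULL, top_path = NULL) {
  if (!is.null(group_matrix) && !is.null(matrix_path)) {
    df <- data.frame(subject_id = group_matrix$subject_ids,
                     group_matrix$values, check.names = FALSE)
    utils::write.csv(df, matrix_path, row.names = FALSE)
  }
  if (!is.null(top) && !is.null(top_path))
    utils::write.csv(top$ranking, top_path, row.names = FALSE)
  invisible(NULL)
}
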