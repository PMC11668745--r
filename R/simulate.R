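#' Specify a two-group synthetic rs-fMRI cohort
#'
#' Defines the generative conditions for a cohort of ROI time-series
#' matrices whose between-ROI correlation differs by group inside planted
#' ROI blocks. Signals are zero-mean Gaussian, colored spatially by a
#' block correlation matrix and temporally by an AR(1) process, which is
#' the statistical structure the downstream pipeline consumes (it operates
#' on connectivity, never on amplitude).
#'
#' @param n_rois number of regions of interest (default 116, the AAL atlas).
#' @param n_timepoints time points per subject (default 200).
#' @param n_subjects_per_group named integer vector of length 2; names are
#'   the group labels.
#' @param block_partition integer vector of length `n_rois` assigning each
#'   ROI to a connectivity block (labels `1..B`); the same partition is used
#'   for both groups. Default: four equal contiguous blocks.
#' @param within_block_corr_by_group list of two numeric vectors (one per
#'   group, same order as `n_subjects_per_group`), each of length `B`,
#'   giving the within-block correlation level in `[0, 1)` for that group.
#'   Between-block correlation is zero.
#' @param noise_ar1 AR(1) temporal autocorrelation coefficient in `[0, 1)`.
#' @param roi_names optional ROI labels; default [roi_labels()].
#' @param seed integer seed making the cohort fully reproducible.
#' @return an object of class `cohort_spec`.
#' @examples
#' sp <- cohort_spec(n_rois = 8, n_timepoints = 50,
#'                   n_subjects_per_group = c(g1 = 3, g2 = 3),
#'                   block_partition = rep(1:2, each = 4),
#'                   within_block_corr_by_group = list(c(0.8, 0.2), c(0.2, 0.8)))
#' cohort <- simulate_cohort(sp)
#' @export
cohort_spec <- function(n_rois = 116L, n_timepoints = 200L,
                        n_subjects_per_group = c(groupA = 20L, groupB = 20L),
                        block_partition = NULL,
                        within_block_corr_by_group = NULL,
                        noise_ar1 = 0.3,
                        roi_names = NULL,
                        seed = 1L) {
  n_rois <- as.integer(n_rois); n_timepoints <- as.integer(n_timepoints)
  stopifnot(n_rois >= 2L, n_timepoints >= 2L,
            length(n_subjects_per_group) == 2L,
            all(n_subjects_per_group >= 1L),
            is.numeric(noise_ar1), noise_ar1 >= 0, noise_ar1 < 1)
  if (is.null(names(n_subjects_per_group)))
    names(n_subjects_per_group) <- c("groupA", "groupB")
  if (anyDuplicated(names(n_subjects_per_group)))
    stop("the two group labels must be distinct")
  if (is.null(block_partition)) {
    n_blocks <- min(4L, n_rois)
    block_partition <- sort(rep_len(seq_len(n_blocks), n_rois))
  }
  block_partition <- as.integer(block_partition)
  if (length(block_partition) != n_rois)
    stop("block_partition must assign every ROI to exactly one block")
  blocks <- sort(unique(block_partition))
  if (!identical(blocks, seq_along(blocks)))
    stop("block labels must be 1..B with every block non-empty")
  if (is.null(within_block_corr_by_group)) {
    base <- rep_len(c(0.6, 0.3), length(blocks))
    within_block_corr_by_group <- list(base, rev(base))
  }
  stopifnot(length(within_block_corr_by_group) == 2L)
  for (g in 1:2) {
    rho <- within_block_corr_by_group[[g]]
    if (length(rho) != length(blocks) || any(rho < 0) || any(rho >= 1))
      stop("each group needs one correlation level in [0,1) per block")
  }
  if (is.null(roi_names)) roi_names <- roi_labels(n_rois)
  stopifnot(length(roi_names) == n_rois, !anyDuplicated(roi_names))
  spec <- structure(list(
    n_rois = n_rois, n_timepoints = n_timepoints,
    n_subjects_per_group = n_subjects_per_group,
    block_partition = block_partition,
    within_block_corr_by_group = within_block_corr_by_group,
    noise_ar1 = noise_ar1, roi_names = roi_names, seed = as.integer(seed)
  ), class = "cohort_spec")
  # positive definiteness of both implied correlation matrices is part of
  # the contract: fail at construction, naming the offending block
  for (g in 1:2) .cohort_chol(spec, g)
  spec
}

# block-correlation matrix for group g and its Cholesky factor; a
# compound-symmetric block with rho in [0,1) is PD, but arbitrary user
# partitions/levels are still verified numerically
.cohort_sigma <- function(spec, g) {
  rho <- spec$within_block_corr_by_group[[g]]
  sig <- diag(spec$n_rois)
  for (b in seq_along(rho)) {
    idx <- which(spec$block_partition == b)
    sig[idx, idx] <- rho[b]
    diag(sig)[idx] <- 1
  }
  sig
}

.cohort_chol <- function(spec, g) {
  sig <- .cohort_sigma(spec, g)
  L <- tryCatch(chol(sig), error = function(e) NULL)
  if (is.null(L)) {
    rho <- spec$within_block_corr_by_group[[g]]
    bad <- which.max(rho)
    stop(sprintf(paste0("implied correlation matrix for group '%s' is not ",
                        "positive definite (check block %d, level %.3f)"),
                 names(spec$n_subjects_per_group)[g], bad, rho[bad]))
  }
  t(L) # lower triangular
}

#' One subject's ROI time-series matrix
#'
#' Container for a single subject's BOLD signal matrix (ROIs in rows, time
#' points in columns) with ROI labels and a group tag.
#'
#' @param subject_id character scalar.
#' @param group character scalar group label.
#' @param signals numeric `n_rois x n_timepoints` matrix, no missing values.
#' @param roi_names character vector, one label per signal row.
#' @return an object of class `roi_ts`.
#' @export
roi_ts <- function(subject_id, group, signals, roi_names = rownames(signals)) {
  signals <- as.matrix(signals)
  if (is.null(roi_names)) roi_names <- roi_labels(nrow(signals))
  stopifnot(is.character(subject_id), length(subject_id) == 1L,
            is.character(group), length(group) == 1L,
            is.numeric(signals), length(roi_names) == nrow(signals),
            !anyDuplicated(roi_names))
  if (anyNA(signals)) stop("signals contain missing values")
  rownames(signals) <- roi_names
  flat <- roi_names[apply(signals, 1L, stats::var) == 0]
  structure(list(subject_id = subject_id, group = group,
                 signals = signals, roi_labels = roi_names,
                 constant_rois = flat),
            class = "roi_ts")
}

#' @export
print.roi_ts <- function(x, ...) {
  cat(sprintf("<roi_ts> subject %s (group %s): %d ROIs x %d time points\n",
              x$subject_id, x$group, nrow(x$signals), ncol(x$signals)))
  if (length(x$constant_rois))
    cat("  constant rows:", paste(x$constant_rois, collapse = ", "), "\n")
  invisible(x)
}

#' Simulate a two-group cohort of ROI time series
#'
#' Draws every subject's `n_rois x n_timepoints` signal matrix under the
#' spec's group block-correlation structure: innovations are iid standard
#' normal, filtered to a stationary AR(1) along time, then colored across
#' ROIs by the Cholesky factor of the group correlation matrix. Marginal
#' between-ROI correlation equals the specified block matrix at any lag-0
#' cut; temporal autocorrelation is `noise_ar1` at lag 1.
#'
#' @param spec a [cohort_spec()].
#' @return list of [roi_ts()] objects, groups concatenated in spec order.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  groups <- names(spec$n_subjects_per_group)
  out <- vector("list", sum(spec$n_subjects_per_group))
  k <- 0L
  for (g in 1:2) {
    L <- .cohort_chol(spec, g)
    for (s in seq_len(spec$n_subjects_per_group[[g]])) {
      z <- .ar1_matrix(spec$n_rois, spec$n_timepoints, spec$noise_ar1)
      k <- k + 1L
      out[[k]] <- roi_ts(sprintf("sub-%s-%03d", groups[g], s), groups[g],
                         L %*% z, spec$roi_names)
    }
  }
  out
}

# rows: independent stationary AR(1) series with unit marginal variance
.ar1_matrix <- function(n, t, phi) {
  e <- matrix(stats::rnorm(n * t), n, t)
  if (phi == 0) return(e)
  x <- e
  x[, 1] <- e[, 1]
  w <- sqrt(1 - phi^2)
  for (j in 2:t) x[, j] <- phi * x[, j - 1] + w * e[, j]
  x
}

#' Specify a planted item-response matrix for the latent space model
#'
#' Generative conditions for a continuous subjects-by-ROI response matrix
#' with known latent structure: per-ROI main effects, per-subject main
#' effects, ROI latent positions clustered around given 2-D centers, and
#' subject latent positions, combined as
#' `y_ij = theta_j + beta_i - ||u_j - v_i|| + noise`.
#'
#' @param n_subjects,n_rois matrix dimensions (subjects are rows).
#' @param latent_dim latent space dimension (default 2).
#' @param true_theta_sd,true_beta_sd standard deviations of the simulated
#'   ROI and subject main effects.
#' @param cluster_centers list of numeric vectors of length `latent_dim`;
#'   ROIs are assigned to centers round-robin and their latent positions
#'   drawn around the assigned center.
#' @param cluster_sd spread of ROI positions around their center.
#' @param noise_sd residual standard deviation, must be positive.
#' @param seed integer seed.
#' @return object of class `item_response_spec`.
#' @export
item_response_spec <- function(n_subjects, n_rois, latent_dim = 2L,
                               true_theta_sd = 1, true_beta_sd = 1,
                               cluster_centers = list(c(0, 0)),
                               cluster_sd = 0.5,
                               noise_sd = 0.1, seed = 1L) {
  stopifnot(n_subjects >= 1L, n_rois >= 1L, latent_dim >= 1L,
            true_theta_sd > 0, true_beta_sd > 0, cluster_sd >= 0,
            noise_sd > 0, length(cluster_centers) >= 1L)
  if (!all(lengths(cluster_centers) == latent_dim))
    stop("every cluster center must have length latent_dim")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_rois = as.integer(n_rois),
                 latent_dim = as.integer(latent_dim),
                 true_theta_sd = true_theta_sd, true_beta_sd = true_beta_sd,
                 cluster_centers = cluster_centers, cluster_sd = cluster_sd,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "item_response_spec")
}

#' Simulate an item-response matrix with planted latent structure
#'
#' @param spec an [item_response_spec()].
#' @return list with `Y` (`n_subjects x n_rois` matrix) and `truth`, a list
#'   holding the drawn `theta` (per ROI), `beta` (per subject), `U`
#'   (`n_rois x latent_dim`), `V` (`n_subjects x latent_dim`), the ROI
#'   cluster assignment and the noise-free mean matrix — everything a
#'   recovery test needs.
#' @export
simulate_item_response <- function(spec) {
  stopifnot(inherits(spec, "item_response_spec"))
  set.seed(spec$seed)
  R <- spec$n_rois; N <- spec$n_subjects; d <- spec$latent_dim
  theta <- stats::rnorm(R, 0, spec$true_theta_sd)
  beta <- stats::rnorm(N, 0, spec$true_beta_sd)
  centers <- do.call(rbind, spec$cluster_centers)
  assign <- rep_len(seq_len(nrow(centers)), R)
  U <- centers[assign, , drop = FALSE] +
    matrix(stats::rnorm(R * d, 0, spec$cluster_sd), R, d)
  V <- matrix(stats::rnorm(N * d), N, d)
  D <- latent_distances(U, V) # R x N
  mean_mat <- outer(beta, theta, `+`) - t(D) # N x R
  Y <- mean_mat + matrix(stats::rnorm(N * R, 0, spec$noise_sd), N, R)
  dimnames(Y) <- list(sprintf("sub-%03d", seq_len(N)), roi_labels(R))
  list(Y = Y,
       truth = list(theta = theta, beta = beta, U = U, V = V,
                    cluster = assign, mean = mean_mat))
}

#' Euclidean distances between item and respondent latent positions
#'
#' @param U `R x d` matrix of item (ROI) positions.
#' @param V `N x d` matrix of respondent (subject) positions.
#' @return `R x N` matrix with entry `(j, i) = ||u_j - v_i||`.
#' @export
latent_distances <- function(U, V) {
  U <- as.matrix(U); V <- as.matrix(V)
  stopifnot(ncol(U) == ncol(V))
  d2 <- outer(rowSums(U^2), rowSums(V^2), `+`) - 2 * tcrossprod(U, V)
  sqrt(pmax(d2, 0))
}

#' Write a cohort to per-subject CSV files plus a manifest
#'
#' Each subject file has the ROI label in the first column and one column
#' per time point; the manifest lists `subject_id, group, path` (paths
#' relative to the manifest's directory).
#'
#' @param cohort list of [roi_ts()] objects.
#' @param dir output directory, created if needed.
#' @return path of the manifest CSV, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(length(cohort) >= 1L,
            all(vapply(cohort, inherits, logical(1), "roi_ts")))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(ts) {
    file <- paste0(ts$subject_id, ".csv")
    df <- data.frame(roi = ts$roi_labels, ts$signals,
                     check.names = FALSE, row.names = NULL)
    colnames(df) <- c("roi", sprintf("t%d", seq_len(ncol(ts$signals))))
    utils::write.csv(df, file.path(dir, file), row.names = FALSE)
    data.frame(subject_id = ts$subject_id, group = ts$group, path = file)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param manifest_path path to the manifest CSV (`subject_id, group, path`
#'   columns; subject paths resolved relative to the manifest directory).
#' @return list of [roi_ts()] objects, validated and label-aligned: every
#'   subject must carry the identical ordered ROI label set.
#' @export
read_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop("manifest not found: ", manifest_path)
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "path")
  if (!all(need %in% names(manifest)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  base <- dirname(manifest_path)
  cohort <- lapply(seq_len(nrow(manifest)), function(i) {
    p <- manifest$path[i]
    if (!file.exists(p)) p <- file.path(base, manifest$path[i])
    if (!file.exists(p))
      stop(sprintf("subject file missing for '%s': %s",
                   manifest$subject_id[i], manifest$path[i]))
    df <- utils::read.csv(p, check.names = FALSE, stringsAsFactors = FALSE)
    sig <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(sig) <- "double"
    roi_ts(as.character(manifest$subject_id[i]),
           as.character(manifest$group[i]), sig, as.character(df[[1]]))
  })
  labs <- lapply(cohort, `[[`, "roi_labels")
  ok <- vapply(labs, identical, logical(1), labs[[1]])
  if (!all(ok))
    stop("ROI labels differ across subjects: ",
         paste(manifest$subject_id[!ok], collapse = ", "))
  cohort
}
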