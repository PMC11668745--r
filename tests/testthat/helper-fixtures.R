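# Shared fixtures, all generated in code at test time.

# small two-group cohort; gap = within-block correlation difference
# between groups (0 -> no signal)
small_cohort_spec <- function(gap = 0.5, n_per_group = 15L, n_rois = 16L,
                              n_timepoints = 120L, seed = 21L) {
  lo <- 0.2; hi <- lo + gap
  cohort_spec(n_rois = n_rois, n_timepoints = n_timepoints,
              n_subjects_per_group = c(a = n_per_group, b = n_per_group),
              block_partition = rep(1:2, each = n_rois / 2),
              within_block_corr_by_group = list(c(hi, lo), c(lo, hi)),
              seed = seed)
}

# classifier settings sized for the small cohort
small_attn_config <- function(seed = 3L, cv_folds = 5L, dropout = 0.5) {
  attn_config(n_heads = 8L, d_k = 2L, dropout = dropout, batch_size = 8L,
              learning_rate = 0.01, max_epochs = 40L, patience = 8L,
              cv_folds = cv_folds, seed = seed)
}

# random row-stochastic attention matrices with metadata
random_attn_matrices <- function(n_subjects, n_rois, group = "g",
                                 seed = 1L, labels = roi_labels(n_rois)) {
  set.seed(seed)
  lapply(seq_len(n_subjects), function(i) {
    w <- matrix(stats::rexp(n_rois^2), n_rois, n_rois)
    w <- w / rowSums(w)
    attn_matrix(w, sprintf("sub-%s-%03d", group, i), group,
                comparison = c("a", "b"), roi_names = labels)
  })
}

# fully scalar, loop-based forward pass of the multi-head model;
# independent oracle for multi_head_forward()
loop_multihead <- function(X, params, cfg) {
  R <- nrow(X); m <- cfg$model_width; dk <- cfg$d_k; H <- cfg$n_heads
  T1 <- matrix(0, R, m)
  for (r in 1:R) for (c in 1:m) {
    s <- params$b_e[c]
    for (k in 1:R) s <- s + X[r, k] * params$W_e[k, c]
    T1[r, c] <- s
  }
  matmul <- function(A, B) {
    C <- matrix(0, nrow(A), ncol(B))
    for (i in seq_len(nrow(A))) for (j in seq_len(ncol(B))) {
      s <- 0
      for (k in seq_len(ncol(A))) s <- s + A[i, k] * B[k, j]
      C[i, j] <- s
    }
    C
  }
  O <- matrix(0, R, m)
  weights <- vector("list", H)
  for (h in 1:H) {
    cols <- ((h - 1) * dk + 1):(h * dk)
    Q <- matmul(T1, params$W_q[, cols, drop = FALSE])
    K <- matmul(T1, params$W_k[, cols, drop = FALSE])
    V <- matmul(T1, params$W_v[, cols, drop = FALSE])
    A <- matrix(0, R, R)
    for (i in 1:R) {
      sc <- numeric(R)
      for (j in 1:R) sc[j] <- sum(Q[i, ] * K[j, ]) / sqrt(dk)
      e <- exp(sc - max(sc))
      A[i, ] <- e / sum(e)
    }
    weights[[h]] <- A
    O[, cols] <- matmul(A, V)
  }
  Z <- sweep(matmul(O, params$W_o), 2, params$b_o, `+`)
  H1 <- pmax(sweep(matmul(Z, params$W_1), 2, params$b_1, `+`), 0)
  pool <- colMeans(H1)
  logits <- as.vector(pool %*% params$W_2) + params$b_2
  list(logits = logits, per_head_weights = weights)
}

# random 2-D rotation (det +1) or reflection (det -1)
random_orthogonal2 <- function(reflect = FALSE) {
  a <- stats::runif(1, 0, 2 * pi)
  Q <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  if (reflect) Q[, 2] <- -Q[, 2]
  Q
}

# effective sample size from the autocorrelation function
ess <- function(x) {
  a <- stats::acf(x, plot = FALSE, lag.max = min(200, length(x) - 1))$acf[-1]
  pos <- which(a < 0.05)[1]
  if (is.na(pos)) pos <- length(a)
  length(x) / (1 + 2 * sum(a[seq_len(pos)]))
}
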