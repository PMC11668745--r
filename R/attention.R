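#' Self-attention classifier configuration
#'
#' Hyperparameters of the single-layer multi-head self-attention binary
#' classifier. Defaults follow the settings that proved robust for 116-ROI
#' inputs: 128 heads of width `d_k = 2` (model width 256), batch size 8,
#' dropout 0.9 on the perceptron hidden layer, Adam at learning rate 0.01,
#' cross-entropy loss, 10-fold cross-validation.
#'
#' @param n_heads number of attention heads H.
#' @param d_k per-head query/key/value width (d_v = d_k).
#' @param dropout dropout rate in `[0, 1)` applied to the perceptron
#'   hidden layer during training only.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param max_epochs maximum training epochs.
#' @param patience early-stopping patience (epochs without validation-loss
#'   improvement) used during cross-validation folds.
#' @param cv_folds number of cross-validation folds (>= 2).
#' @param seed integer seed for fold splits and weight initialization.
#' @return object of class `attn_config`; `model_width` is `n_heads * d_k`.
#' @export
attn_config <- function(n_heads = 128L, d_k = 2L, dropout = 0.9,
                        batch_size = 8L, learning_rate = 0.01,
                        max_epochs = 100L, patience = 10L,
                        cv_folds = 10L, seed = 1L) {
  stopifnot(n_heads >= 1L, d_k >= 1L, dropout >= 0, dropout < 1,
            batch_size >= 1L, learning_rate > 0, max_epochs >= 1L,
            cv_folds >= 2L)
  structure(list(n_heads = as.integer(n_heads), d_k = as.integer(d_k),
                 model_width = as.integer(n_heads) * as.integer(d_k),
                 dropout = dropout, batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed)),
            class = "attn_config")
}

#' Scaled dot-product attention
#'
#' `weights = softmax(Q K' / sqrt(d_k))` row-wise, `output = weights V`.
#' Every weight row sums to one (softmax image).
#'
#' @param Q,K,V matrices with equal row count; `Q`,`K` share `d_k` columns.
#' @param d_k scaling dimension (> 0); defaults to `ncol(K)`.
#' @return list with `weights` (row-stochastic) and `output`.
#' @examples
#' scaled_attention(matrix(0, 3, 1), matrix(1, 3, 1), diag(3))$weights
#' @export
scaled_attention <- function(Q, K, V, d_k = ncol(K)) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  if (d_k <= 0) stop("d_k must be positive")
  stopifnot(nrow(Q) == nrow(K), nrow(K) == nrow(V), ncol(Q) == ncol(K))
  W <- .softmax_rows(tcrossprod(Q, K) / sqrt(d_k))
  list(weights = W, output = W %*% V)
}

.softmax_rows <- function(S) {
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  E / rowSums(E)
}

# Xavier-initialized parameter set for inputs with n_tokens tokens of
# feature width n_tokens (one token per ROI, features = its matrix row)
init_attn_params <- function(n_tokens, cfg) {
  m <- cfg$model_width
  xav <- function(r, c) matrix(stats::rnorm(r * c, sd = sqrt(2 / (r + c))), r, c)
  list(W_e = xav(n_tokens, m), b_e = numeric(m),
       W_q = xav(m, m), W_k = xav(m, m), W_v = xav(m, m),
       W_o = xav(m, m), b_o = numeric(m),
       W_1 = xav(m, m), b_1 = numeric(m),
       W_2 = xav(m, 2L), b_2 = numeric(2L))
}

.head_cols <- function(h, d_k) ((h - 1L) * d_k + 1L):(h * d_k)

# full forward pass for one subject; keeps every intermediate needed by
# the analytic backward pass. mask: dropout mask matrix or NULL (eval).
.attn_forward <- function(X, params, cfg, mask = NULL) {
  p <- params; m <- cfg$model_width; dk <- cfg$d_k; H <- cfg$n_heads
  R <- nrow(X)
  T1 <- X %*% p$W_e + rep(p$b_e, each = R)
  Qa <- T1 %*% p$W_q; Ka <- T1 %*% p$W_k; Va <- T1 %*% p$W_v
  O <- matrix(0, R, m)
  A <- vector("list", H)
  for (h in seq_len(H)) {
    cols <- .head_cols(h, dk)
    at <- scaled_attention(Qa[, cols, drop = FALSE],
                           Ka[, cols, drop = FALSE],
                           Va[, cols, drop = FALSE], dk)
    A[[h]] <- at$weights
    O[, cols] <- at$output
  }
  Z <- O %*% p$W_o + rep(p$b_o, each = R)
  H1pre <- Z %*% p$W_1 + rep(p$b_1, each = R)
  H1 <- pmax(H1pre, 0)
  keep <- 1 - cfg$dropout
  H1d <- if (is.null(mask)) H1 else H1 * mask / keep
  pool <- colMeans(H1d)
  logits <- drop(pool %*% p$W_2) + p$b_2
  list(T1 = T1, Qa = Qa, Ka = Ka, Va = Va, A = A, O = O, Z = Z,
       H1pre = H1pre, H1 = H1, H1d = H1d, pool = pool, logits = logits,
       mask = mask, X = X)
}

# analytic gradients of the cross-entropy loss for one subject
.attn_backward <- function(fw, y, params, cfg) {
  p <- params; dk <- cfg$d_k; H <- cfg$n_heads
  R <- nrow(fw$X); m <- cfg$model_width
  pr <- exp(fw$logits - max(fw$logits)); pr <- pr / sum(pr)
  dlogits <- pr; dlogits[y] <- dlogits[y] - 1
  g <- list()
  g$W_2 <- outer(fw$pool, dlogits); g$b_2 <- dlogits
  dpool <- drop(p$W_2 %*% dlogits)
  dH1d <- matrix(dpool, R, m, byrow = TRUE) / R
  keep <- 1 - cfg$dropout
  dH1 <- if (is.null(fw$mask)) dH1d else dH1d * fw$mask / keep
  dH1pre <- dH1 * (fw$H1pre > 0)
  g$W_1 <- crossprod(fw$Z, dH1pre); g$b_1 <- colSums(dH1pre)
  dZ <- tcrossprod(dH1pre, p$W_1)
  g$W_o <- crossprod(fw$O, dZ); g$b_o <- colSums(dZ)
  dO <- tcrossprod(dZ, p$W_o)
  dQa <- matrix(0, R, m); dKa <- matrix(0, R, m); dVa <- matrix(0, R, m)
  for (h in seq_len(H)) {
    cols <- .head_cols(h, dk)
    A <- fw$A[[h]]
    dOh <- dO[, cols, drop = FALSE]
    Vh <- fw$Va[, cols, drop = FALSE]
    dA <- tcrossprod(dOh, Vh)
    dVa[, cols] <- crossprod(A, dOh)
    dS <- A * (dA - rowSums(dA * A)) / sqrt(dk)
    dQa[, cols] <- dS %*% fw$Ka[, cols, drop = FALSE]
    dKa[, cols] <- crossprod(dS, fw$Qa[, cols, drop = FALSE])
  }
  g$W_q <- crossprod(fw$T1, dQa)
  g$W_k <- crossprod(fw$T1, dKa)
  g$W_v <- crossprod(fw$T1, dVa)
  dT1 <- tcrossprod(dQa, p$W_q) + tcrossprod(dKa, p$W_k) +
    tcrossprod(dVa, p$W_v)
  g$W_e <- crossprod(fw$X, dT1); g$b_e <- colSums(dT1)
  g
}

.attn_loss <- function(logits, y) {
  z <- logits - max(logits)
  -(z[y] - log(sum(exp(z))))
}

#' Multi-head self-attention forward pass (evaluation mode)
#'
#' Projects one subject's `R x R` input matrix to `R` tokens, runs all
#' heads of scaled dot-product attention, concatenates head outputs,
#' applies the output projection and the perceptron, mean-pools over
#' tokens and emits two-class logits. Dropout is off.
#'
#' @param tokens one subject's `R x R` input matrix (FCN adjacency or
#'   correlation matrix), one token per ROI.
#' @param params parameter list as produced by training.
#' @param cfg an [attn_config()].
#' @return list with `logits` (length 2) and `per_head_weights` (list of
#'   `H` row-stochastic `R x R` matrices).
#' @export
multi_head_forward <- function(tokens, params, cfg) {
  tokens <- as.matrix(tokens)
  if (nrow(tokens) != ncol(tokens))
    stop("tokens must be a square ROI x ROI matrix")
  if (nrow(params$W_e) != nrow(tokens))
    stop("parameter shapes do not match the input token count")
  fw <- .attn_forward(tokens, params, cfg, mask = NULL)
  list(logits = fw$logits, per_head_weights = fw$A)
}

#' Attention distribution matrix
#'
#' Element-wise mean of one layer's `H` row-stochastic head weight
#' matrices; the result is itself row-stochastic and summarizes, for each
#' ROI row, how the model distributes attention over all ROIs.
#'
#' @param per_head_weights non-empty list of row-stochastic matrices.
#' @param subject_id,group,comparison metadata carried on the result.
#' @param roi_names optional ROI labels.
#' @return object of class `attn_matrix` with fields `values`,
#'   `subject_id`, `group`, `comparison`.
#' @export
attention_distribution <- function(per_head_weights, subject_id = NA_character_,
                                   group = NA_character_,
                                   comparison = c(NA_character_, NA_character_),
                                   roi_names = NULL) {
  if (!length(per_head_weights)) stop("empty head list")
  M <- Reduce(`+`, per_head_weights) / length(per_head_weights)
  attn_matrix(M, subject_id, group, comparison, roi_names)
}

#' @rdname attention_distribution
#' @param values row-stochastic nonnegative matrix.
#' @export
attn_matrix <- function(values, subject_id = NA_character_,
                        group = NA_character_,
                        comparison = c(NA_character_, NA_character_),
                        roi_names = NULL) {
  values <- as.matrix(values)
  if (min(values) < 0 || max(values) > 1 + 1e-8)
    stop("attention entries must lie in [0, 1]")
  if (max(abs(rowSums(values) - 1)) > 1e-5)
    stop("attention rows must sum to 1 within 1e-5")
  if (is.null(roi_names)) roi_names <- rownames(values)
  if (is.null(roi_names)) roi_names <- roi_labels(nrow(values))
  dimnames(values) <- list(roi_names, roi_names)
  structure(list(values = values, subject_id = subject_id, group = group,
                 comparison = comparison, roi_labels = roi_names),
            class = "attn_matrix")
}

#' @export
print.attn_matrix <- function(x, ...) {
  cat(sprintf("<attn_matrix> subject %s (group %s), %d x %d\n",
              x$subject_id, x$group, nrow(x$values), ncol(x$values)))
  invisible(x)
}

# one Adam update over the averaged minibatch gradients
.adam_step <- function(params, grads, state, lr, t,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# train on xs[train_idx]; if val_idx is non-empty, early-stop on
# validation loss with cfg$patience. Returns params and loss history.
.attn_train <- function(xs, ys, cfg, train_idx, val_idx = integer(0)) {
  R <- nrow(xs[[1]])
  params <- init_attn_params(R, cfg)
  zeros <- lapply(params, function(x) x * 0)
  state <- list(m = zeros, v = zeros)
  keep <- 1 - cfg$dropout
  best <- list(loss = Inf, params = params, epoch = 0L)
  wait <- 0L; t_adam <- 0L
  hist <- numeric(0)
  for (epoch in seq_len(cfg$max_epochs)) {
    idx <- sample(train_idx)
    batches <- split(idx, ceiling(seq_along(idx) / cfg$batch_size))
    ep_loss <- 0
    for (b in batches) {
      grads <- NULL
      bl <- 0
      for (i in b) {
        mask <- if (cfg$dropout > 0)
          matrix(stats::rbinom(R * cfg$model_width, 1L, keep),
                 R, cfg$model_width) else NULL
        fw <- .attn_forward(xs[[i]], params, cfg, mask)
        bl <- bl + .attn_loss(fw$logits, ys[i])
        g <- .attn_backward(fw, ys[i], params, cfg)
        grads <- if (is.null(grads)) g else
          Map(`+`, grads, g)
      }
      if (!all(vapply(grads, function(x) all(is.finite(x)), logical(1))) ||
          !is.finite(bl))
        stop("non-finite loss/gradient during training (epoch ", epoch, ")")
      grads <- lapply(grads, `/`, length(b))
      t_adam <- t_adam + 1L
      up <- .adam_step(params, grads, state, cfg$learning_rate, t_adam)
      params <- up$params; state <- up$state
      ep_loss <- ep_loss + bl
    }
    hist <- c(hist, ep_loss / length(train_idx))
    if (length(val_idx)) {
      vl <- mean(vapply(val_idx, function(i)
        .attn_loss(.attn_forward(xs[[i]], params, cfg)$logits, ys[i]),
        numeric(1)))
      if (vl < best$loss - 1e-6) {
        best <- list(loss = vl, params = params, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
  }
  if (length(val_idx)) list(params = best$params, history = hist,
                            best_epoch = best$epoch)
  else list(params = params, history = hist, best_epoch = length(hist))
}

.attn_predict <- function(xs, params, cfg, idx = seq_along(xs)) {
  vapply(idx, function(i)
    which.max(.attn_forward(xs[[i]], params, cfg)$logits), integer(1))
}

#' Train the self-attention classifier and extract attention matrices
#'
#' Runs stratified k-fold cross-validation (cross-entropy loss, Adam,
#' minibatches, dropout on the perceptron hidden layer, early stopping on
#' the held-out fold) to estimate classification accuracy, then trains a
#' final model on all subjects and feeds every subject through it in
#' evaluation mode to extract the per-subject attention distribution
#' matrix.
#'
#' @param xs list of per-subject square input matrices (all same size),
#'   e.g. FCN adjacencies from [mapper_fcn()] or values of
#'   [pearson_matrix()] / [fisher_z()].
#' @param groups character/factor vector of group labels, exactly two
#'   distinct values.
#' @param cfg an [attn_config()].
#' @param roi_names optional ROI labels for the attention matrices.
#' @return list with `cv_accuracy` (mean over folds), `fold_accuracies`,
#'   `attn_matrices` (one [attn_matrix()] per subject), `params` (final
#'   model), `comparison` (ordered group pair), `history` (final-model
#'   epoch losses), `best_epochs` (per fold).
#' @export
train_and_extract <- function(xs, groups, cfg = attn_config(),
                              roi_names = NULL) {
  stopifnot(inherits(cfg, "attn_config"), length(xs) == length(groups),
            length(xs) >= cfg$cv_folds)
  groups <- as.character(groups)
  levs <- sort(unique(groups))
  if (length(levs) != 2L)
    stop("exactly two group labels required, got: ",
         paste(levs, collapse = ", "))
  dims <- vapply(xs, function(x) dim(as.matrix(x)), integer(2))
  if (any(dims != dims[1, 1]))
    stop("all subject matrices must be square and share one ROI count")
  xs <- lapply(xs, as.matrix)
  ys <- match(groups, levs)
  if (is.null(roi_names)) roi_names <- rownames(xs[[1]])
  if (is.null(roi_names)) roi_names <- roi_labels(nrow(xs[[1]]))

  set.seed(cfg$seed)
  folds <- .stratified_folds(ys, cfg$cv_folds)
  acc <- numeric(cfg$cv_folds); best_epochs <- integer(cfg$cv_folds)
  for (k in seq_len(cfg$cv_folds)) {
    te <- which(folds == k); tr <- which(folds != k)
    fit <- .attn_train(xs, ys, cfg, tr, val_idx = te)
    acc[k] <- mean(.attn_predict(xs, fit$params, cfg, te) == ys[te])
    best_epochs[k] <- fit$best_epoch
  }
  final <- .attn_train(xs, ys, cfg, seq_along(xs))
  attn <- lapply(seq_along(xs), function(i) {
    mh <- multi_head_forward(xs[[i]], final$params, cfg)
    attention_distribution(mh$per_head_weights,
                           subject_id = names(xs)[i] %||% sprintf("sub-%03d", i),
                           group = groups[i], comparison = levs,
                           roi_names = roi_names)
  })
  list(cv_accuracy = mean(acc), fold_accuracies = acc,
       attn_matrices = attn, params = final$params, comparison = levs,
       history = final$history, best_epochs = best_epochs)
}

# balanced fold labels per class, shuffled
.stratified_folds <- function(ys, k) {
  folds <- integer(length(ys))
  for (cl in unique(ys)) {
    idx <- sample(which(ys == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Cross-validated head-count search
#'
#' Convenience routine evaluating [train_and_extract()] over a grid of
#' head counts `H` (with `d_k` fixed), returning the CV accuracy per `H`.
#' Not run by default anywhere; provided for parameter exploration.
#'
#' @param xs,groups,cfg as in [train_and_extract()].
#' @param heads integer vector of head counts to try.
#' @return data.frame with columns `n_heads`, `cv_accuracy`.
#' @export
search_heads <- function(xs, groups, cfg = attn_config(),
                         heads = c(16L, 32L, 64L, 128L)) {
  res <- lapply(heads, function(h) {
    c2 <- attn_config(n_heads = h, d_k = cfg$d_k, dropout = cfg$dropout,
                      batch_size = cfg$batch_size,
                      learning_rate = cfg$learning_rate,
                      max_epochs = cfg$max_epochs, patience = cfg$patience,
                      cv_folds = cfg$cv_folds, seed = cfg$seed)
    data.frame(n_heads = h,
               cv_accuracy = train_and_extract(xs, groups, c2)$cv_accuracy)
  })
  do.call(rbind, res)
}
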