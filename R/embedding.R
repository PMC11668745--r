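#' Embed ROIs into two dimensions
#'
#' Treats each ROI as one point whose feature vector is its time course and
#' embeds the point cloud into the plane with one of three families:
#' `linear` (principal component projection, deterministic), `stochastic`
#' (t-SNE: neighborhood distances converted to conditional probabilities
#' matched by a heavy-tailed low-dimensional kernel), or `topological`
#' (UMAP-style: a fuzzy k-nearest-neighbor simplicial set laid out by
#' minimizing fuzzy cross-entropy). The stochastic and topological
#' optimizers are full-batch gradient descent, so a fixed seed gives
#' bit-identical coordinates.
#'
#' @param ts a [roi_ts()] (or a plain numeric matrix, rows = points).
#' @param method `"linear"`, `"stochastic"` or `"topological"`.
#' @param params method hyperparameters; recognized entries are
#'   `perplexity` (stochastic, default 10), `n_neighbors` (topological,
#'   default 15), `min_dist` (topological, default 0.1), and `n_iter`.
#' @param seed integer seed for the stochastic/topological initializers.
#' @return object of class `roi_embedding`: list with `coords`
#'   (`n_rois x 2`, rownames = ROI labels), `method`, `params`, `seed`.
#' @export
embed_rois <- function(ts, method = c("linear", "stochastic", "topological"),
                       params = list(), seed = 1L) {
  method <- match.arg(method)
  x <- if (inherits(ts, "roi_ts")) ts$signals else as.matrix(ts)
  labels <- if (inherits(ts, "roi_ts")) ts$roi_labels else rownames(x)
  if (is.null(labels)) labels <- roi_labels(nrow(x))
  if (ncol(x) < 3L) stop("need at least 3 time points to embed")
  coords <- switch(method,
    linear = .embed_pca(x),
    stochastic = .embed_tsne(x, params, seed),
    topological = .embed_umap(x, params, seed))
  if (!all(is.finite(coords))) stop("embedding produced non-finite coordinates")
  dimnames(coords) <- list(labels, c("dim1", "dim2"))
  structure(list(coords = coords, method = method, params = params,
                 seed = as.integer(seed)),
            class = "roi_embedding")
}

#' @export
print.roi_embedding <- function(x, ...) {
  cat(sprintf("<roi_embedding> %s, %d points\n", x$method, nrow(x$coords)))
  invisible(x)
}

# principal-component projection: centered data onto top-2 right singular
# vectors; sign fixed so the largest-magnitude loading of each axis is
# positive (determinism across LAPACK builds)
.embed_pca <- function(x) {
  xc <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(xc, nu = 0, nv = 2)
  v <- sv$v
  for (j in 1:2) if (v[which.max(abs(v[, j])), j] < 0) v[, j] <- -v[, j]
  xc %*% v
}

.pairdist2 <- function(x) {
  s <- rowSums(x^2)
  d2 <- outer(s, s, `+`) - 2 * tcrossprod(x)
  d2[d2 < 0] <- 0
  diag(d2) <- 0
  d2
}

# binary search for the Gaussian bandwidth matching a target perplexity
.tsne_p_matrix <- function(d2, perplexity) {
  n <- nrow(d2)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    lo <- -Inf; hi <- Inf; beta <- 1
    for (iter in 1:60) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { h <- 0 } else {
        h <- log(sw) + beta * sum(di * w) / sw
      }
      if (abs(h - logU) < 1e-5) break
      if (h > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    w <- exp(-di * beta)
    P[i, -i] <- if (sum(w) > 0) w / sum(w) else 1 / (n - 1)
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

.embed_tsne <- function(x, params, seed) {
  n <- nrow(x)
  perplexity <- params$perplexity %||% min(10, max(2, (n - 1) / 3))
  n_iter <- params$n_iter %||% 500L
  if (3 * perplexity > n - 1) perplexity <- max(2, (n - 1) / 3)
  P <- .tsne_p_matrix(.pairdist2(x), perplexity)
  set.seed(seed)
  y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  gain <- matrix(1, n, 2); inc <- matrix(0, n, 2)
  eta <- 100; momentum <- 0.5
  for (it in seq_len(n_iter)) {
    ex <- if (it <= 100) 4 else 1 # early exaggeration
    d2 <- .pairdist2(y)
    num <- 1 / (1 + d2); diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    W <- (ex * P - Q) * num
    grad <- 4 * (diag(rowSums(W)) %*% y - W %*% y)
    gain <- ifelse(sign(grad) != sign(inc), gain + 0.2, gain * 0.8)
    gain[gain < 0.01] <- 0.01
    inc <- momentum * inc - eta * gain * grad
    y <- y + inc
    y <- sweep(y, 2, colMeans(y))
    if (it == 250) momentum <- 0.8
  }
  y
}

# fit the low-dimensional kernel 1/(1 + a d^(2b)) to the min_dist plateau
.umap_ab <- function(min_dist, spread = 1) {
  d <- seq(0, spread * 3, length.out = 300)
  target <- ifelse(d <= min_dist, 1, exp(-(d - min_dist) / spread))
  obj <- function(p) {
    v <- 1 / (1 + exp(p[1]) * d^(2 * exp(p[2])))
    sum((v - target)^2)
  }
  p <- stats::optim(c(0, 0), obj)$par
  c(a = exp(p[1]), b = exp(p[2]))
}

# fuzzy simplicial set: smooth-kNN weights, symmetrized by fuzzy union
.umap_graph <- function(d2, k) {
  n <- nrow(d2)
  d <- sqrt(d2)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ord <- order(d[i, -i])
    nn <- setdiff(order(d[i, ]), i)[seq_len(k)]
    dn <- d[i, nn]
    rho <- min(dn[dn > 0], Inf)
    if (!is.finite(rho)) rho <- 0
    # binary search sigma so sum(exp(-(d - rho)/sigma)) = log2(k)
    target <- log2(k)
    lo <- 1e-10; hi <- Inf; sigma <- 1
    for (iter in 1:60) {
      s <- sum(exp(-pmax(dn - rho, 0) / sigma))
      if (abs(s - target) < 1e-5) break
      if (s > target) { hi <- sigma; sigma <- (sigma + lo) / 2 }
      else { lo <- sigma; sigma <- if (is.finite(hi)) (sigma + hi) / 2 else sigma * 2 }
    }
    W[i, nn] <- exp(-pmax(dn - rho, 0) / sigma)
  }
  W + t(W) - W * t(W)
}

.embed_umap <- function(x, params, seed) {
  n <- nrow(x)
  k <- min(params$n_neighbors %||% 15L, n - 1L)
  min_dist <- params$min_dist %||% 0.1
  n_iter <- params$n_iter %||% 300L
  ab <- .umap_ab(min_dist)
  a <- ab[["a"]]; b <- ab[["b"]]
  W <- .umap_graph(.pairdist2(x), k)
  set.seed(seed)
  y <- .embed_pca(x)
  y <- y / max(1e-12, stats::sd(y)) * 2 + matrix(stats::rnorm(n * 2, sd = 1e-3), n, 2)
  eta0 <- 0.3
  for (it in seq_len(n_iter)) {
    eta <- eta0 * (1 - (it - 1) / n_iter) + 1e-3
    d2 <- .pairdist2(y)
    d2b <- d2^b
    v <- 1 / (1 + a * d2b)          # low-dim membership
    dv_dd2 <- -(a * b * d2^(pmax(b - 1, 0)) ) * v^2
    diag(dv_dd2) <- 0
    dce_dv <- -(W / pmax(v, 1e-9) - (1 - W) / pmax(1 - v, 1e-3))
    G <- dce_dv * dv_dd2
    diag(G) <- 0
    grad <- 2 * (diag(rowSums(G)) %*% y - G %*% y)
    nrm <- sqrt(rowSums(grad^2))
    grad <- grad / pmax(nrm / 4, 1)  # clip per-point step
    y <- y - eta * grad
    y <- sweep(y, 2, colMeans(y))
  }
  y
}

`%||%` <- function(a, b) if (is.null(a)) b else a
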