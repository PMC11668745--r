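#' MCMC configuration for the continuous latent space item-response model
#'
#' Defaults follow the settings used for 116-ROI group matrices: 55,000
#' iterations, 5,000 burn-in, thinning 5 (10,000 retained draws),
#' random-walk jump scales 0.005 for the ROI effects, subject effects and
#' ROI positions, 0.003 for subject positions, Inv-Gamma(0.001, 0.001)
#' variance priors, and N(0, 1) priors for the subject effects and the
#' latent positions.
#'
#' @param n_iterations,burn_in,thin chain length, discarded prefix and
#'   retention interval; `(n_iterations - burn_in) / thin` draws are kept.
#' @param jump_theta,jump_beta,jump_u,jump_v random-walk proposal standard
#'   deviations per block.
#' @param a_sigma,b_sigma Inv-Gamma prior shape/rate shared by the
#'   likelihood variance and the ROI-effect variance.
#' @param prior_beta_sd,prior_latent_sd prior standard deviations of the
#'   subject effects and of every latent coordinate.
#' @param proposal `"random_walk"` (default) or `"independent"` (proposals
#'   drawn from the priors, in which case the jump scales are unused).
#' @param seed integer seed.
#' @return object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iterations = 55000L, burn_in = 5000L, thin = 5L,
                        jump_theta = 0.005, jump_beta = 0.005,
                        jump_u = 0.005, jump_v = 0.003,
                        a_sigma = 0.001, b_sigma = 0.001,
                        prior_beta_sd = 1, prior_latent_sd = 1,
                        proposal = c("random_walk", "independent"),
                        seed = 1L) {
  proposal <- match.arg(proposal)
  stopifnot(burn_in < n_iterations, thin >= 1L,
            jump_theta > 0, jump_beta > 0, jump_u > 0, jump_v > 0,
            a_sigma > 0, b_sigma > 0, prior_beta_sd > 0, prior_latent_sd > 0)
  structure(list(n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 jump_theta = jump_theta, jump_beta = jump_beta,
                 jump_u = jump_u, jump_v = jump_v,
                 a_sigma = a_sigma, b_sigma = b_sigma,
                 prior_beta_sd = prior_beta_sd,
                 prior_latent_sd = prior_latent_sd,
                 proposal = proposal, seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Log-likelihood of the continuous LSIRM
#'
#' Sum over all cells of the normal log-density of `y_ij` at mean
#' `theta_j + beta_i - ||u_j - v_i||` with variance `sigma2`. Invariant
#' under any joint rigid motion (rotation, reflection, translation)
#' applied to all `u_j` and `v_i` simultaneously, since only the
#' distances enter.
#'
#' @param Y `N x R` response matrix (subjects in rows, ROIs in columns) or
#'   a [build_group_matrix()] result.
#' @param theta length-`R` ROI main effects.
#' @param beta length-`N` subject main effects.
#' @param U `R x d` ROI latent positions.
#' @param V `N x d` subject latent positions.
#' @param sigma2 likelihood variance (> 0).
#' @return scalar log-likelihood.
#' @export
lsirm_log_likelihood <- function(Y, theta, beta, U, V, sigma2) {
  Y <- .lsirm_Y(Y)
  if (sigma2 <= 0) stop("sigma2 must be positive")
  stopifnot(length(theta) == ncol(Y), length(beta) == nrow(Y),
            nrow(U) == ncol(Y), nrow(V) == nrow(Y))
  M <- .lsirm_mean(theta, beta, U, V)
  sum(stats::dnorm(Y, M, sqrt(sigma2), log = TRUE))
}

.lsirm_Y <- function(Y) {
  if (inherits(Y, "group_rep_matrix")) Y$values else as.matrix(Y)
}

# N x R mean matrix
.lsirm_mean <- function(theta, beta, U, V) {
  outer(beta, theta, `+`) - t(latent_distances(U, V))
}

# deterministic warm start by multidimensional unfolding: main effects
# estimated from row/column means give a proxy subject-ROI distance
# matrix; double-centering its square yields approximate inner products
# between centered subject and ROI positions, factored by SVD
.lsirm_warm_start <- function(Y, d) {
  N <- nrow(Y); R <- ncol(Y)
  beta0 <- rowMeans(Y) - mean(Y) / 2
  theta0 <- colMeans(Y) - mean(Y) / 2
  Dhat <- outer(beta0, theta0, `+`) - Y
  Dhat <- pmax(Dhat - min(Dhat), 0)
  Jn <- diag(N) - 1 / N; Jr <- diag(R) - 1 / R
  B <- -0.5 * Jn %*% Dhat^2 %*% Jr
  s <- svd(B, nu = d, nv = d)
  sc <- sqrt(s$d[seq_len(d)])
  V0 <- s$u %*% diag(sc, d)
  U0 <- s$v %*% diag(sc, d)
  D0 <- t(latent_distances(U0, V0))
  theta0 <- colMeans(Y + D0) - mean(beta0)
  list(theta = theta0, beta = beta0, U = U0, V = V0)
}

#' Fit the continuous LSIRM by Metropolis-within-Gibbs MCMC
#'
#' Each iteration cycles through elementwise Metropolis-Hastings updates
#' of the ROI effects `theta`, subject effects `beta`, ROI positions `u_j`
#' and subject positions `v_i` (random-walk proposals at the configured
#' jump scales; each coordinate's acceptance depends only on its own row
#' or column of residuals, so the updates are vectorized), a Gibbs draw of
#' the ROI-effect variance from its Inv-Gamma full conditional, and a
#' Gibbs draw of the likelihood variance from its Inv-Gamma full
#' conditional. States after burn-in are retained every `thin` iterations.
#'
#' @param Y `N x R` matrix or [build_group_matrix()] result.
#' @param cfg an [mcmc_config()].
#' @param latent_dim latent space dimension (default 2).
#' @param align run [procrustes_align()] on the retained draws and store
#'   aligned posterior means (default `TRUE`).
#' @param init `"unfolding"` (default) starts the chain from a
#'   deterministic multidimensional-unfolding configuration computed from
#'   `Y` (plus a small seeded jitter), the standard warm start for latent
#'   space models: random dispersed starts can lock a peaked posterior
#'   into mirror-assignment local modes. `"random"` draws the start near
#'   the origin instead.
#' @param init_latent_scale for `init = "random"`, positions start from a
#'   normal with sd `prior_latent_sd * init_latent_scale` (default 0.1).
#' @param fix optional named list freezing blocks at given values
#'   (`theta`, `beta`, `U`, `V`, `sigma2`, `sigma_theta2`); frozen blocks
#'   are neither initialized randomly nor updated. Intended for
#'   limit-case validation (e.g. the conjugate reduction where only
#'   `theta` moves).
#' @return object of class `lsirm_posterior`: matrices of retained draws
#'   `theta` (draws x R), `beta` (draws x N), arrays `U`
#'   (draws x R x d) and `V`, vectors `sigma2` and `sigma_theta2`,
#'   per-block `acceptance` rates, and (if aligned) posterior means
#'   `U_mean`, `V_mean`.
#' @export
run_lsirm <- function(Y, cfg = mcmc_config(), latent_dim = 2L, align = TRUE,
                      fix = list(), init = c("unfolding", "random"),
                      init_latent_scale = 0.1) {
  init <- match.arg(init)
  roi_lab <- if (inherits(Y, "group_rep_matrix")) Y$roi_labels
  sub_ids <- if (inherits(Y, "group_rep_matrix")) Y$subject_ids
  Y <- .lsirm_Y(Y)
  if (!all(is.finite(Y))) stop("Y must be finite")
  stopifnot(inherits(cfg, "mcmc_config"), latent_dim >= 1L)
  N <- nrow(Y); R <- ncol(Y); d <- as.integer(latent_dim)
  if (is.null(roi_lab)) roi_lab <- colnames(Y) %||% roi_labels(R)
  if (is.null(sub_ids)) sub_ids <- rownames(Y) %||% sprintf("sub-%03d", 1:N)

  set.seed(cfg$seed)
  rw <- cfg$proposal == "random_walk"
  free <- function(nm) is.null(fix[[nm]])
  # initialization: deterministic unfolding warm start with seeded
  # jitter, or random draws near the origin (unless a block is frozen)
  warm <- if (init == "unfolding") .lsirm_warm_start(Y, d)
  sigma_theta2 <- fix$sigma_theta2 %||% 1
  isd <- cfg$prior_latent_sd * init_latent_scale
  jit <- function(n) stats::rnorm(n, 0, 0.01)
  theta <- fix$theta %||%
    if (is.null(warm)) stats::rnorm(R, 0, sqrt(sigma_theta2)) else
      warm$theta + jit(R)
  beta <- fix$beta %||%
    if (is.null(warm)) stats::rnorm(N, 0, cfg$prior_beta_sd) else
      warm$beta + jit(N)
  U <- fix$U %||%
    if (is.null(warm)) matrix(stats::rnorm(R * d, 0, isd), R, d) else
      warm$U + matrix(jit(R * d), R, d)
  V <- fix$V %||%
    if (is.null(warm)) matrix(stats::rnorm(N * d, 0, isd), N, d) else
      warm$V + matrix(jit(N * d), N, d)
  sigma2 <- fix$sigma2 %||% stats::var(as.vector(Y))
  if (sigma2 == 0) sigma2 <- 1

  D <- t(latent_distances(U, V))              # N x R
  Res <- Y - (outer(beta, theta, `+`) - D)    # residuals
  n_keep <- (cfg$n_iterations - cfg$burn_in) %/% cfg$thin
  keep_theta <- matrix(NA_real_, n_keep, R)
  keep_beta <- matrix(NA_real_, n_keep, N)
  keep_U <- array(NA_real_, c(n_keep, R, d))
  keep_V <- array(NA_real_, c(n_keep, N, d))
  keep_s2 <- numeric(n_keep); keep_st2 <- numeric(n_keep)
  acc <- c(theta = 0, beta = 0, u = 0, v = 0)
  kept <- 0L

  for (iter in seq_len(cfg$n_iterations)) {
    # --- theta_j | rest (affects only column j) -------------------------
    if (free("theta")) {
    th_star <- if (rw) theta + stats::rnorm(R, 0, cfg$jump_theta)
               else stats::rnorm(R, 0, sqrt(sigma_theta2))
    delta <- th_star - theta
    dll <- (2 * delta * colSums(Res) - N * delta^2) / (2 * sigma2)
    if (rw) dll <- dll - (th_star^2 - theta^2) / (2 * sigma_theta2)
    a <- log(stats::runif(R)) < dll
    theta[a] <- th_star[a]
    Res[, a] <- Res[, a] - rep(delta[a], each = N)
    acc["theta"] <- acc["theta"] + mean(a)
    }

    # --- beta_i | rest (affects only row i) -----------------------------
    if (free("beta")) {
    be_star <- if (rw) beta + stats::rnorm(N, 0, cfg$jump_beta)
               else stats::rnorm(N, 0, cfg$prior_beta_sd)
    delta <- be_star - beta
    dll <- (2 * delta * rowSums(Res) - R * delta^2) / (2 * sigma2)
    if (rw) dll <- dll - (be_star^2 - beta^2) / (2 * cfg$prior_beta_sd^2)
    a <- log(stats::runif(N)) < dll
    beta[a] <- be_star[a]
    Res[a, ] <- Res[a, ] - delta[a]
    acc["beta"] <- acc["beta"] + mean(a)
    }

    # --- u_j | rest (affects only column j) -----------------------------
    if (free("U")) {
    U_star <- if (rw) U + matrix(stats::rnorm(R * d, 0, cfg$jump_u), R, d)
              else matrix(stats::rnorm(R * d, 0, cfg$prior_latent_sd), R, d)
    D_star <- t(latent_distances(U_star, V))
    dD <- D_star - D
    dll <- -(2 * colSums(Res * dD) + colSums(dD^2)) / (2 * sigma2)
    if (rw) dll <- dll - (rowSums(U_star^2) - rowSums(U^2)) /
      (2 * cfg$prior_latent_sd^2)
    a <- log(stats::runif(R)) < dll
    U[a, ] <- U_star[a, ]
    Res[, a] <- Res[, a] + dD[, a, drop = FALSE]
    D[, a] <- D_star[, a, drop = FALSE]
    acc["u"] <- acc["u"] + mean(a)
    }

    # --- v_i | rest (affects only row i) --------------------------------
    if (free("V")) {
    V_star <- if (rw) V + matrix(stats::rnorm(N * d, 0, cfg$jump_v), N, d)
              else matrix(stats::rnorm(N * d, 0, cfg$prior_latent_sd), N, d)
    D_star <- t(latent_distances(U, V_star))
    dD <- D_star - D
    dll <- -(2 * rowSums(Res * dD) + rowSums(dD^2)) / (2 * sigma2)
    if (rw) dll <- dll - (rowSums(V_star^2) - rowSums(V^2)) /
      (2 * cfg$prior_latent_sd^2)
    a <- log(stats::runif(N)) < dll
    V[a, ] <- V_star[a, ]
    Res[a, ] <- Res[a, ] + dD[a, , drop = FALSE]
    D[a, ] <- D_star[a, , drop = FALSE]
    acc["v"] <- acc["v"] + mean(a)
    }

    # --- Gibbs: sigma_theta2, then sigma2 -------------------------------
    if (free("sigma_theta2"))
      sigma_theta2 <- 1 / stats::rgamma(1, cfg$a_sigma + R / 2,
                                        cfg$b_sigma + sum(theta^2) / 2)
    if (free("sigma2"))
      sigma2 <- 1 / stats::rgamma(1, cfg$a_sigma + N * R / 2,
                                  cfg$b_sigma + sum(Res^2) / 2)

    if (!all(is.finite(Res)) || !is.finite(sigma2))
      stop("divergent (non-finite) MCMC state at iteration ", iter)

    if (iter > cfg$burn_in && (iter - cfg$burn_in) %% cfg$thin == 0L) {
      kept <- kept + 1L
      keep_theta[kept, ] <- theta
      keep_beta[kept, ] <- beta
      keep_U[kept, , ] <- U
      keep_V[kept, , ] <- V
      keep_s2[kept] <- sigma2
      keep_st2[kept] <- sigma_theta2
    }
  }
  post <- structure(list(theta = keep_theta, beta = keep_beta,
                         U = keep_U, V = keep_V,
                         sigma2 = keep_s2, sigma_theta2 = keep_st2,
                         acceptance = acc / cfg$n_iterations,
                         n_draws = n_keep, latent_dim = d,
                         roi_labels = roi_lab, subject_ids = sub_ids,
                         config = cfg, aligned = FALSE),
                    class = "lsirm_posterior")
  if (align) post <- procrustes_align(post)
  post
}

#' @export
print.lsirm_posterior <- function(x, ...) {
  cat(sprintf("<lsirm_posterior> %d draws, %d ROIs x %d subjects, d = %d\n",
              x$n_draws, ncol(x$theta), ncol(x$beta), x$latent_dim))
  cat("  acceptance:",
      paste(sprintf("%s %.2f", names(x$acceptance), x$acceptance),
            collapse = ", "),
      if (x$aligned) "\n  draws Procrustes-aligned\n" else "\n")
  invisible(x)
}

#' Procrustes-align retained latent-position draws
#'
#' The likelihood depends on the latent positions only through distances,
#' so each draw's joint (ROI + subject) configuration is identified only
#' up to rigid motion. Every draw is rotated/reflected (least-squares
#' orthogonal Procrustes via SVD; optionally translated to the reference
#' centroid first) onto a reference configuration. Reference is the first
#' retained draw; a second pass re-aligns against the mean of the aligned
#' draws when `refine = TRUE`. Relative distances are untouched.
#'
#' @param posterior an [run_lsirm()] result.
#' @param translate also match centroids (default `FALSE`: the zero-mean
#'   priors already pin the configuration center softly).
#' @param refine second alignment pass against the aligned mean.
#' @return the posterior with `U`, `V` replaced by aligned draws,
#'   `U_mean`/`V_mean` posterior means added and `aligned = TRUE`.
#' @export
procrustes_align <- function(posterior, translate = FALSE, refine = TRUE) {
  stopifnot(inherits(posterior, "lsirm_posterior"), posterior$n_draws >= 1L)
  R <- dim(posterior$U)[2]; N <- dim(posterior$V)[2]
  joint <- function(k) rbind(posterior$U[k, , ], posterior$V[k, , ])
  ref <- joint(1L)
  if (max(stats::dist(ref)) == 0)
    warning("degenerate all-equal reference configuration; identity used")
  align_all <- function(ref) {
    for (k in seq_len(posterior$n_draws)) {
      C <- joint(k)
      A <- .procrustes_rotate(C, ref, translate)
      posterior$U[k, , ] <<- A[seq_len(R), , drop = FALSE]
      posterior$V[k, , ] <<- A[R + seq_len(N), , drop = FALSE]
    }
  }
  align_all(ref)
  if (refine && posterior$n_draws > 1L) {
    mref <- rbind(apply(posterior$U, c(2, 3), mean),
                  apply(posterior$V, c(2, 3), mean))
    align_all(mref)
  }
  posterior$U_mean <- apply(posterior$U, c(2, 3), mean)
  posterior$V_mean <- apply(posterior$V, c(2, 3), mean)
  rownames(posterior$U_mean) <- posterior$roi_labels
  posterior$aligned <- TRUE
  posterior
}

# least-squares orthogonal (rotation + reflection) match of C onto ref
.procrustes_rotate <- function(C, ref, translate = FALSE) {
  mC <- colMeans(C); mR <- colMeans(ref)
  if (translate) { C <- sweep(C, 2, mC); ref2 <- sweep(ref, 2, mR) }
  else ref2 <- ref
  s <- svd(crossprod(C, ref2))
  A <- C %*% (s$u %*% t(s$v))
  if (translate) A <- sweep(A, 2, mR, `+`)
  A
}

#' Oblimin rotation of latent ROI positions
#'
#' Applies an oblique gradient-projection rotation minimizing the oblimin
#' criterion (gamma = 0, i.e. quartimin) to the posterior-mean ROI
#' position matrix, the standard post-hoc rotation for interpretability.
#' The rotation is oblique, so origin distances may change; both before
#' and after distances are returned.
#'
#' @param positions `R x d` matrix of aligned posterior-mean ROI
#'   positions, or an aligned [run_lsirm()] posterior (its `U_mean`).
#' @param max_iter,tol gradient-projection iteration controls. The
#'   optimizer is restarted from its own output until the criterion stops
#'   improving (line searches can stall short of the optimum).
#' @return list with `rotated` (`R x d`), `rotation` (the `d x d` matrix
#'   `M` with `rotated = positions %*% M`), `criterion_before`,
#'   `criterion_after`, `origin_dist_before`, `origin_dist_after`.
#' @export
rotate_positions <- function(positions, max_iter = 1000L, tol = 1e-10) {
  if (inherits(positions, "lsirm_posterior")) {
    if (!positions$aligned) stop("align the posterior first")
    positions <- positions$U_mean
  }
  L0 <- as.matrix(positions)
  k <- ncol(L0)
  L <- L0
  M <- diag(k)
  f <- .quartimin(L0)$f
  for (restart in 1:25) {
    fit <- .gpf_oblq(L, max_iter = max_iter, tol = tol)
    M <- M %*% t(solve(fit$Tm))
    L <- fit$L
    if (f - fit$f < 1e-9 * (1 + abs(f))) { f <- fit$f; break }
    f <- fit$f
  }
  list(rotated = L, rotation = M,
       criterion_before = .quartimin(L0)$f,
       criterion_after = f,
       origin_dist_before = sqrt(rowSums(L0^2)),
       origin_dist_after = sqrt(rowSums(L^2)))
}

# quartimin criterion and gradient (oblimin with gamma = 0)
.quartimin <- function(L) {
  L2 <- L^2
  k <- ncol(L)
  Nm <- matrix(1, k, k) - diag(k)
  X <- L2 %*% Nm
  list(f = sum(L2 * X) / 4, Gq = L * X)
}

# oblique gradient projection (Jennrich 2002 GPFoblq)
.gpf_oblq <- function(A, max_iter = 500L, tol = 1e-8) {
  k <- ncol(A)
  Tm <- diag(k)
  al <- 1
  Ti <- solve(Tm)
  L <- A %*% t(Ti)
  vg <- .quartimin(L)
  f <- vg$f
  G <- -t(t(L) %*% vg$Gq %*% Ti)
  for (it in seq_len(max_iter)) {
    Gp <- G - Tm %*% diag(colSums(Tm * G), k)
    s <- sqrt(sum(Gp^2))
    if (s < tol) break
    al <- 2 * al
    for (inner in 1:20) {
      X <- Tm - al * Gp
      Xt <- X %*% diag(1 / sqrt(colSums(X^2)), k)
      Xi <- solve(Xt)
      Lt <- A %*% t(Xi)
      vt <- .quartimin(Lt)
      if (vt$f < f - 0.5 * s^2 * al) break
      al <- al / 2
    }
    Tm <- Xt; f <- vt$f; L <- Lt
    G <- -t(t(L) %*% vt$Gq %*% Xi)
  }
  list(L = L, Tm = Tm, f = f)
}

#' Rank ROIs by latent-position origin proximity
#'
#' ROIs whose aligned posterior-mean latent positions sit near the origin
#' interact consistently with all of the group's subjects. ROIs are
#' sorted by ascending Euclidean norm; the `near_origin` flag marks the
#' lowest quartile of norms, or everything within `radius` when given.
#'
#' @param posterior an aligned [run_lsirm()] result, or a bare `R x d`
#'   position matrix with rownames.
#' @param radius optional absolute distance threshold overriding the
#'   quartile rule.
#' @return data.frame with columns `roi`, `distance`, `rank`,
#'   `near_origin`, sorted by rank.
#' @export
origin_proximity <- function(posterior, radius = NULL) {
  if (inherits(posterior, "lsirm_posterior")) {
    if (!posterior$aligned) stop("align the posterior first")
    U <- posterior$U_mean
    labs <- posterior$roi_labels
  } else {
    U <- as.matrix(posterior)
    labs <- rownames(U) %||% roi_labels(nrow(U))
  }
  d <- sqrt(rowSums(U^2))
  ord <- order(d, labs)
  flag <- if (is.null(radius)) {
    k <- floor(0.25 * length(d))
    seq_along(d) <= k
  } else d[ord] <= radius
  data.frame(roi = labs[ord], distance = d[ord],
             rank = seq_along(d), near_origin = flag, row.names = NULL)
}

#' Write posterior draws and position summaries to CSV
#'
#' One CSV per parameter block (`theta`, `beta`, `U`, `V`, `sigma2`,
#' `sigma_theta2`) plus a summary CSV of posterior-mean ROI positions and
#' origin distances.
#'
#' @param posterior an aligned [run_lsirm()] result.
#' @param dir output directory, created if needed.
#' @return invisibly the directory.
#' @export
write_lsirm <- function(posterior, dir) {
  stopifnot(inherits(posterior, "lsirm_posterior"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, nm) utils::write.csv(as.data.frame(x),
                                        file.path(dir, nm), row.names = FALSE)
  colnames(posterior$theta) <- posterior$roi_labels
  colnames(posterior$beta) <- posterior$subject_ids
  w(posterior$theta, "theta.csv"); w(posterior$beta, "beta.csv")
  d <- posterior$latent_dim
  for (ax in seq_len(d)) {
    w(`colnames<-`(posterior$U[, , ax], posterior$roi_labels),
      sprintf("U_dim%d.csv", ax))
    w(`colnames<-`(posterior$V[, , ax], posterior$subject_ids),
      sprintf("V_dim%d.csv", ax))
  }
  w(data.frame(sigma2 = posterior$sigma2,
               sigma_theta2 = posterior$sigma_theta2), "variances.csv")
  if (posterior$aligned) {
    pos <- data.frame(roi = posterior$roi_labels, posterior$U_mean,
                      origin_distance = sqrt(rowSums(posterior$U_mean^2)))
    colnames(pos)[2:(1 + d)] <- sprintf("dim%d", seq_len(d))
    w(pos, "roi_positions.csv")
  }
  invisible(dir)
}
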