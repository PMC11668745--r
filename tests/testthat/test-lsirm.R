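test_that("log-likelihood matches closed forms and loop evaluation", {
  # exact-fit single cell: density of 0 under Normal(0, sigma2)
  s2 <- 0.3
  ll <- lsirm_log_likelihood(matrix(1.7), theta = 0.7, beta = 1,
                             U = matrix(0, 1, 2), V = matrix(0, 1, 2),
                             sigma2 = s2)
  expect_equal(ll, -0.5 * log(2 * pi * s2), tolerance = 1e-12)

  # 2 x 2 matrix equals the four-term loop computation
  set.seed(37)
  Y <- matrix(rnorm(4), 2, 2)
  theta <- rnorm(2); beta <- rnorm(2)
  U <- matrix(rnorm(4), 2, 2); V <- matrix(rnorm(4), 2, 2)
  got <- lsirm_log_likelihood(Y, theta, beta, U, V, 0.5)
  want <- 0
  for (i in 1:2) for (j in 1:2) {
    mu <- theta[j] + beta[i] - sqrt(sum((U[j, ] - V[i, ])^2))
    want <- want + dnorm(Y[i, j], mu, sqrt(0.5), log = TRUE)
  }
  expect_equal(got, want, tolerance = 1e-12)
  expect_error(lsirm_log_likelihood(Y, theta, beta, U, V, 0), "positive")
})

test_that("log-likelihood is invariant under joint rigid motions", {
  set.seed(38)
  Y <- matrix(rnorm(15), 3, 5)
  theta <- rnorm(5); beta <- rnorm(3)
  U <- matrix(rnorm(10), 5, 2); V <- matrix(rnorm(6), 3, 2)
  base <- lsirm_log_likelihood(Y, theta, beta, U, V, 1)
  for (reflect in c(FALSE, TRUE)) {
    Q <- random_orthogonal2(reflect)
    shift <- rnorm(2)
    U2 <- sweep(U %*% Q, 2, shift, `+`)
    V2 <- sweep(V %*% Q, 2, shift, `+`)
    expect_equal(lsirm_log_likelihood(Y, theta, beta, U2, V2, 1), base,
                 tolerance = 1e-12)
  }
})

test_that("retained-draw count identity holds exactly", {
  expect_identical((55000L - 5000L) %/% 5L, 10000L)
  set.seed(39)
  Y <- matrix(rnorm(12), 3, 4)
  cfg <- mcmc_config(n_iterations = 730, burn_in = 130, thin = 3, seed = 2)
  post <- run_lsirm(Y, cfg, align = FALSE)
  expect_identical(nrow(post$theta), 200L)
  expect_identical(dim(post$U), c(200L, 4L, 2L))
  expect_identical(length(post$sigma2), 200L)
})

test_that("chains are reproducible from the seed", {
  set.seed(40)
  Y <- matrix(rnorm(40), 5, 8)
  cfg <- mcmc_config(n_iterations = 600, burn_in = 100, thin = 2,
                     jump_theta = 0.1, jump_beta = 0.1, jump_u = 0.1,
                     jump_v = 0.1, seed = 33)
  p1 <- run_lsirm(Y, cfg)
  p2 <- run_lsirm(Y, cfg)
  expect_identical(p1$theta, p2$theta)
  expect_identical(p1$U, p2$U)
  expect_identical(p1$sigma2, p2$sigma2)
  cfg2 <- cfg; cfg2$seed <- 34L
  expect_false(identical(run_lsirm(Y, cfg2)$theta, p1$theta))
})

test_that("conjugate reduction recovers the closed-form theta posterior", {
  set.seed(41)
  N <- 40L; R <- 6L
  theta_t <- rnorm(R); beta_t <- rnorm(N)
  s2 <- 0.25; st2 <- 1
  Y <- outer(beta_t, theta_t, `+`) + matrix(rnorm(N * R, 0, sqrt(s2)), N, R)
  cfg <- mcmc_config(n_iterations = 6000, burn_in = 1000, thin = 1,
                     jump_theta = 0.2, seed = 2)
  post <- run_lsirm(Y, cfg, align = FALSE,
                    fix = list(beta = beta_t, U = matrix(0, R, 2),
                               V = matrix(0, N, 2), sigma2 = s2,
                               sigma_theta2 = st2))
  prec <- N / s2 + 1 / st2
  closed_mean <- (colSums(Y - beta_t) / s2) / prec
  closed_sd <- sqrt(1 / prec)
  for (j in seq_len(R)) {
    draws <- post$theta[, j]
    mcse <- closed_sd / sqrt(ess(draws))
    expect_lt(abs(mean(draws) - closed_mean[j]), 3 * mcse + 1e-8)
  }
})

test_that("procrustes alignment undoes random rotations and reflections", {
  set.seed(42)
  R <- 8L; N <- 5L; K <- 100L
  C0 <- matrix(rnorm((R + N) * 2), R + N, 2)
  U <- array(0, c(K, R, 2)); V <- array(0, c(K, N, 2))
  for (k in seq_len(K)) {
    Q <- random_orthogonal2(reflect = k %% 2 == 0)
    Ck <- C0 %*% Q
    U[k, , ] <- Ck[1:R, ]; V[k, , ] <- Ck[R + 1:N, ]
  }
  post <- structure(list(U = U, V = V, n_draws = K, latent_dim = 2L,
                         roi_labels = sprintf("r%d", 1:R),
                         subject_ids = sprintf("s%d", 1:N),
                         aligned = FALSE),
                    class = "lsirm_posterior")
  aligned <- procrustes_align(post)
  # first draw is the reference; every aligned draw must equal it
  ref <- rbind(aligned$U[1, , ], aligned$V[1, , ])
  worst <- 0
  for (k in seq_len(K)) {
    Ck <- rbind(aligned$U[k, , ], aligned$V[k, , ])
    worst <- max(worst, max(abs(Ck - ref)))
  }
  expect_lt(worst, 1e-8)
  expect_equal(aligned$U_mean, aligned$U[1, , ],
               ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("alignment preserves within-draw distances", {
  set.seed(43)
  Y <- matrix(rnorm(60), 6, 10)
  cfg <- mcmc_config(n_iterations = 400, burn_in = 100, thin = 3,
                     jump_theta = 0.1, jump_beta = 0.1, jump_u = 0.1,
                     jump_v = 0.1, seed = 5)
  raw <- run_lsirm(Y, cfg, align = FALSE)
  al <- procrustes_align(raw)
  k <- 50L
  d_raw <- latent_distances(raw$U[k, , ], raw$V[k, , ])
  d_al <- latent_distances(al$U[k, , ], al$V[k, , ])
  expect_equal(d_al, d_raw, tolerance = 1e-10)
})

test_that("oblimin rotation lowers the criterion and keeps dimensions", {
  set.seed(44)
  L <- matrix(rnorm(116 * 2, sd = 1.5), 116, 2)
  rot <- rotate_positions(L)
  expect_identical(dim(rot$rotated), c(116L, 2L))
  expect_lte(rot$criterion_after, rot$criterion_before + 1e-12)
  # oracle: evaluate the quartimin criterion directly on both matrices
  crit <- function(M) {
    M2 <- M^2
    sum(M2[, 1] * M2[, 2]) / 2
  }
  expect_equal(rot$criterion_before, crit(L), tolerance = 1e-12)
  expect_equal(rot$criterion_after, crit(rot$rotated), tolerance = 1e-10)
  # rotating an already-optimal configuration changes nothing material
  again <- rotate_positions(rot$rotated)
  expect_equal(again$criterion_after, rot$criterion_after,
               tolerance = 1e-8)
})

test_that("origin proximity ranks by norm and flags the lowest quartile", {
  U <- rbind(c(0, 0), c(3, 0), c(0, 1), c(2, 2), c(0.1, 0),
             c(5, 5), c(1, 1), c(0.5, 0))
  rownames(U) <- sprintf("r%d", 1:8)
  prox <- origin_proximity(U)
  expect_identical(prox$roi[1], "r1") # at the origin
  expect_identical(prox$rank, 1:8)
  expect_true(!is.unsorted(prox$distance))
  expect_identical(sum(prox$near_origin), 2L) # floor(0.25 * 8)
  # radius override
  prox2 <- origin_proximity(U, radius = 1.05)
  expect_setequal(prox2$roi[prox2$near_origin],
                  c("r1", "r3", "r5", "r8"))
})

test_that("posterior draws write to re-readable CSVs", {
  set.seed(45)
  Y <- matrix(rnorm(30), 5, 6)
  cfg <- mcmc_config(n_iterations = 300, burn_in = 100, thin = 2,
                     jump_theta = 0.1, jump_beta = 0.1, jump_u = 0.1,
                     jump_v = 0.1, seed = 6)
  post <- run_lsirm(Y, cfg)
  dir <- withr::local_tempdir()
  write_lsirm(post, dir)
  th <- utils::read.csv(file.path(dir, "theta.csv"), check.names = FALSE)
  expect_identical(dim(th), c(100L, 6L))
  expect_equal(unname(as.matrix(th)), unname(post$theta),
               tolerance = 1e-12)
  pos <- utils::read.csv(file.path(dir, "roi_positions.csv"))
  expect_identical(nrow(pos), 6L)
  expect_equal(pos$origin_distance,
               unname(sqrt(rowSums(post$U_mean^2))), tolerance = 1e-6)
})

test_that("orthogonal matching agrees with vegan's procrustes", {
  skip_if_not_installed("vegan")
  set.seed(60)
  ref <- scale(matrix(rnorm(24), 12, 2), scale = FALSE)
  Q <- random_orthogonal2()
  C <- ref %*% Q
  ours <- fcnfusion:::.procrustes_rotate(C, ref)
  veg <- vegan::procrustes(ref, C, scale = FALSE, symmetric = FALSE)
  expect_equal(unname(ours), unname(veg$Yrot), tolerance = 1e-8)
  expect_lt(max(abs(ours - ref)), 1e-10)
})
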