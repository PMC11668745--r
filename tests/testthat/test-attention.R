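test_that("scaled attention matches hand-computed softmax arithmetic", {
  # zero queries: all scores equal, weights uniform
  sa <- scaled_attention(matrix(0, 3, 2), matrix(rnorm(6), 3, 2), diag(3))
  expect_equal(unname(sa$weights), matrix(1 / 3, 3, 3))
  # R = 2, d_k = 1 scalar evaluation
  sa <- scaled_attention(Q = matrix(c(1, 0), 2, 1),
                         K = matrix(c(1, 0), 2, 1),
                         V = matrix(c(1, 2), 2, 1), d_k = 1)
  w11 <- exp(1) / (exp(1) + exp(0))
  expect_equal(unname(sa$weights),
               rbind(c(w11, 1 - w11), c(0.5, 0.5)), tolerance = 1e-12)
  expect_equal(unname(sa$output),
               rbind(w11 * 1 + (1 - w11) * 2, 1.5), tolerance = 1e-12)
  expect_error(scaled_attention(diag(2), diag(2), diag(2), d_k = 0),
               "positive")
})

test_that("attention weight rows always sum to one", {
  set.seed(23)
  for (rep in 1:5) {
    Q <- matrix(rnorm(12, sd = 3), 4, 3)
    K <- matrix(rnorm(12, sd = 3), 4, 3)
    sa <- scaled_attention(Q, K, matrix(rnorm(8), 4, 2))
    expect_equal(unname(rowSums(sa$weights)), rep(1, 4), tolerance = 1e-12)
    expect_true(all(sa$weights >= 0))
  }
})

test_that("multi-head forward matches the loop-based oracle", {
  set.seed(24)
  cfg <- attn_config(n_heads = 2L, d_k = 1L, dropout = 0, cv_folds = 2L)
  X <- matrix(rnorm(9), 3, 3)
  params <- fcnfusion:::init_attn_params(3L, cfg)
  got <- multi_head_forward(X, params, cfg)
  oracle <- loop_multihead(X, params, cfg)
  expect_equal(got$logits, oracle$logits, tolerance = 1e-10)
  expect_length(got$per_head_weights, 2L)
  for (h in 1:2)
    expect_equal(got$per_head_weights[[h]], oracle$per_head_weights[[h]],
                 tolerance = 1e-10)
})

test_that("every head emits one R x R row-stochastic matrix", {
  set.seed(25)
  cfg <- attn_config(n_heads = 5L, d_k = 2L, cv_folds = 2L)
  X <- matrix(rnorm(36), 6, 6)
  params <- fcnfusion:::init_attn_params(6L, cfg)
  mh <- multi_head_forward(X, params, cfg)
  expect_length(mh$per_head_weights, 5L)
  for (w in mh$per_head_weights) {
    expect_identical(dim(w), c(6L, 6L))
    expect_equal(unname(rowSums(w)), rep(1, 6), tolerance = 1e-10)
  }
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(26)
  cfg <- attn_config(n_heads = 2L, d_k = 2L, dropout = 0, cv_folds = 2L)
  X <- matrix(rnorm(16), 4, 4)
  params <- fcnfusion:::init_attn_params(4L, cfg)
  fw <- fcnfusion:::.attn_forward(X, params, cfg)
  grads <- fcnfusion:::.attn_backward(fw, 2L, params, cfg)
  eps <- 1e-6
  for (nm in names(params)) {
    take <- seq_len(min(4L, length(params[[nm]])))
    for (i in take) {
      p2 <- params
      p2[[nm]][i] <- p2[[nm]][i] + eps
      up <- fcnfusion:::.attn_loss(
        fcnfusion:::.attn_forward(X, p2, cfg)$logits, 2L)
      p2[[nm]][i] <- p2[[nm]][i] - 2 * eps
      dn <- fcnfusion:::.attn_loss(
        fcnfusion:::.attn_forward(X, p2, cfg)$logits, 2L)
      expect_equal(grads[[nm]][i], (up - dn) / (2 * eps),
                   tolerance = 1e-5)
    }
  }
})

test_that("attention distribution averages heads and stays row-stochastic", {
  set.seed(27)
  w1 <- matrix(rexp(16), 4, 4); w1 <- w1 / rowSums(w1)
  w2 <- matrix(rexp(16), 4, 4); w2 <- w2 / rowSums(w2)
  one <- attention_distribution(list(w1))
  expect_equal(unname(one$values), w1)
  u <- matrix(1 / 4, 4, 4)
  expect_equal(unname(attention_distribution(list(u, u, u))$values), u)
  avg <- attention_distribution(list(w1, w2))
  expect_equal(unname(avg$values), (w1 + w2) / 2, tolerance = 1e-12)
  expect_equal(unname(rowSums(avg$values)), rep(1, 4), tolerance = 1e-10)
  expect_error(attention_distribution(list()), "empty")
})

test_that("128-head extraction on a 116-ROI input is 116 x 116", {
  set.seed(28)
  cfg <- attn_config(n_heads = 128L, d_k = 2L, cv_folds = 2L)
  X <- matrix(rnorm(116 * 116, sd = 0.3), 116, 116)
  params <- fcnfusion:::init_attn_params(116L, cfg)
  mh <- multi_head_forward(X, params, cfg)
  expect_length(mh$per_head_weights, 128L)
  am <- attention_distribution(mh$per_head_weights,
                               roi_names = roi_labels(116))
  expect_identical(dim(am$values), c(116L, 116L))
  expect_lt(max(abs(rowSums(am$values) - 1)), 1e-5)
})

test_that("attention distribution is permutation-equivariant", {
  set.seed(29)
  cfg <- attn_config(n_heads = 3L, d_k = 2L, cv_folds = 2L)
  R <- 5L
  X <- matrix(rnorm(R * R), R, R)
  params <- fcnfusion:::init_attn_params(R, cfg)
  perm <- sample(R)
  # permuting input ROIs (rows+cols) with the token projection permuted
  # to match must permute the attention matrix identically
  params_p <- params
  params_p$W_e <- params$W_e[perm, , drop = FALSE]
  base <- attention_distribution(
    multi_head_forward(X, params, cfg)$per_head_weights)$values
  permuted <- attention_distribution(
    multi_head_forward(X[perm, perm], params_p, cfg)$per_head_weights)$values
  expect_equal(unname(permuted), unname(base[perm, perm]),
               tolerance = 1e-10)
})

test_that("training loss decreases on separable data; folds are reproducible", {
  co <- simulate_cohort(small_cohort_spec(n_per_group = 8L,
                                          n_timepoints = 80L))
  xs <- lapply(co, function(ts) pearson_matrix(ts)$values)
  groups <- vapply(co, `[[`, character(1), "group")
  cfg <- small_attn_config(cv_folds = 2L)
  cfg$max_epochs <- 12L
  fit1 <- train_and_extract(xs, groups, cfg)
  expect_lt(mean(tail(fit1$history, 3)), mean(head(fit1$history, 3)))
  # same seed: identical folds, identical model, identical accuracy
  fit2 <- train_and_extract(xs, groups, cfg)
  expect_identical(fit1$fold_accuracies, fit2$fold_accuracies)
  expect_identical(fit1$params, fit2$params)
  for (a in fit1$attn_matrices) {
    expect_lt(max(abs(rowSums(a$values) - 1)), 1e-5)
    expect_true(all(a$values >= 0 & a$values <= 1))
  }
})

test_that("degenerate cohorts are rejected", {
  xs <- replicate(6, diag(3), simplify = FALSE)
  expect_error(train_and_extract(xs, rep("a", 6),
                                 small_attn_config(cv_folds = 2L)),
               "two group labels")
})
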