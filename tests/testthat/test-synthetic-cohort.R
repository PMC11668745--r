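test_that("simulated subjects have the requested dimensions and labels", {
  sp <- cohort_spec(n_rois = 116, n_timepoints = 200,
                    n_subjects_per_group = c(AD = 1, MCI = 2), seed = 4)
  co <- simulate_cohort(sp)
  expect_length(co, 3L)
  expect_true(all(vapply(co, function(ts)
    identical(dim(ts$signals), c(116L, 200L)), logical(1))))
  expect_identical(co[[1]]$roi_labels, roi_labels(116))
  expect_identical(vapply(co, `[[`, character(1), "group"),
                   c("AD", "MCI", "MCI"))
})

test_that("seeds give bit-identical cohorts; different seeds differ", {
  sp <- small_cohort_spec(seed = 8, n_per_group = 2L, n_timepoints = 40L)
  c1 <- simulate_cohort(sp)
  c2 <- simulate_cohort(sp)
  expect_identical(c1[[1]]$signals, c2[[1]]$signals)
  sp2 <- sp; sp2$seed <- 9L
  expect_false(identical(simulate_cohort(sp2)[[1]]$signals,
                         c1[[1]]$signals))
})

test_that("long series reproduce the planted block correlation", {
  sp <- cohort_spec(n_rois = 8, n_timepoints = 100000,
                    n_subjects_per_group = c(a = 1, b = 1),
                    block_partition = rep(1:2, each = 4),
                    within_block_corr_by_group = list(c(0.6, 0.6),
                                                      c(0.6, 0.6)),
                    noise_ar1 = 0.3, seed = 10)
  ts <- simulate_cohort(sp)[[1]]
  r <- stats::cor(t(ts$signals))
  within <- r[1:4, 1:4][upper.tri(diag(4))]
  across <- r[1:4, 5:8]
  expect_lt(max(abs(within - 0.6)), 0.02)
  expect_lt(max(abs(across)), 0.02)
})

test_that("empirical covariance converges to the block covariance", {
  sp <- cohort_spec(n_rois = 6, n_timepoints = 20000,
                    n_subjects_per_group = c(a = 1, b = 1),
                    block_partition = rep(1:2, each = 3),
                    within_block_corr_by_group = list(c(0.7, 0.2),
                                                      c(0.2, 0.7)),
                    seed = 11)
  ts <- simulate_cohort(sp)[[1]]
  emp <- stats::cov(t(ts$signals))
  target <- fcnfusion:::.cohort_sigma(sp, 1)
  expect_lt(max(abs(emp - target)), 0.05)
})

test_that("non-positive-definite block specs are rejected with the block named", {
  # a correlation of 1 within a block is excluded by the [0,1) domain check
  expect_error(
    cohort_spec(n_rois = 4, n_subjects_per_group = c(a = 1, b = 1),
                block_partition = rep(1, 4),
                within_block_corr_by_group = list(1, 0.5)),
    "correlation level")
  expect_error(
    cohort_spec(n_rois = 4, n_subjects_per_group = c(a = 1, b = 1),
                block_partition = c(1, 1, 2, 2),
                within_block_corr_by_group = list(c(0.5), c(0.5))),
    "per block")
})

test_that("item-response draws follow the stated mean structure", {
  sp <- item_response_spec(n_subjects = 7, n_rois = 5,
                           cluster_centers = list(c(1, 0), c(-1, 0)),
                           noise_sd = 1e-9, seed = 3)
  sim <- simulate_item_response(sp)
  tr <- sim$truth
  # loop-based oracle for the mean matrix
  M <- matrix(0, 7, 5)
  for (i in 1:7) for (j in 1:5)
    M[i, j] <- tr$theta[j] + tr$beta[i] -
      sqrt(sum((tr$U[j, ] - tr$V[i, ])^2))
  expect_equal(unname(sim$Y), M, tolerance = 1e-6)
  expect_equal(unname(tr$mean), M, tolerance = 1e-12)
})

test_that("item-response generation is seed-reproducible", {
  sp <- item_response_spec(10, 8, noise_sd = 0.2, seed = 5)
  expect_identical(simulate_item_response(sp)$Y,
                   simulate_item_response(sp)$Y)
})

test_that("planted far clusters depress responses by about the distance gap", {
  sp <- item_response_spec(n_subjects = 200, n_rois = 40,
                           cluster_centers = list(c(0, 0), c(4, 0)),
                           cluster_sd = 0.1, noise_sd = 0.1, seed = 6)
  sim <- simulate_item_response(sp)
  tr <- sim$truth
  # oracle: recompute group means from the emitted truth record
  D <- latent_distances(tr$U, tr$V)
  adj <- sweep(sweep(sim$Y, 1, tr$beta), 2, tr$theta) # = -distance + noise
  for (cl in 1:2) {
    sel <- tr$cluster == cl
    expect_equal(mean(adj[, sel]), -mean(D[sel, ]), tolerance = 0.01)
  }
  # near cluster (centered at origin, subjects ~ N(0,1)) scores higher
  expect_gt(mean(sim$Y[, tr$cluster == 1]) - mean(sim$Y[, tr$cluster == 2]),
            1)
})

test_that("item-response residual variance matches noise_sd^2 within 10%", {
  sp <- item_response_spec(n_subjects = 100, n_rois = 60,
                           noise_sd = 0.3, seed = 12)
  sim <- simulate_item_response(sp)
  res <- sim$Y - sim$truth$mean
  expect_lt(abs(stats::var(as.vector(res)) / 0.3^2 - 1), 0.1)
})

test_that("generic and atlas ROI labels are well-formed", {
  expect_length(roi_labels(116), 116)
  expect_identical(roi_labels(116)[c(37, 57, 98)],
                   c("Hippocampus_L", "Postcentral_L", "Cerebelum_4_5_R"))
  expect_identical(roi_labels(3), c("ROI_001", "ROI_002", "ROI_003"))
  expect_false(anyDuplicated(roi_labels(116)) > 0)
})
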