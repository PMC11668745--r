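adj4 <- function(edges, labels = letters[1:4]) {
  a <- matrix(0, 4, 4, dimnames = list(labels, labels))
  for (e in edges) a[e[1], e[2]] <- a[e[2], e[1]] <- 1
  fcn(a, labels)
}

test_that("identical subject FCNs pass through any threshold <= 1", {
  f <- adj4(list(c(1, 2), c(2, 3)))
  for (thr in c(0.2, 0.5, 1)) {
    s <- group_summary(list(f, f, f), threshold = thr, group = "g")
    expect_equal(s$ratio, f$adjacency)
    expect_equal(s$adjacency, f$adjacency)
  }
})

test_that("surviving edges equal the manual subject count on toy graphs", {
  f1 <- adj4(list(c(1, 2), c(2, 3), c(3, 4)))
  f2 <- adj4(list(c(1, 2), c(2, 3)))
  f3 <- adj4(list(c(1, 2)))
  s <- group_summary(list(f1, f2, f3), threshold = 0.2, group = "g")
  # ratios: ab = 3/3, bc = 2/3, cd = 1/3 -- all >= 0.2
  expect_equal(s$ratio["a", "b"], 1)
  expect_equal(s$ratio["b", "c"], 2 / 3)
  expect_equal(s$ratio["c", "d"], 1 / 3)
  expect_identical(sum(s$adjacency) / 2, 3)
  # at 0.5 the cd edge (1 of 3 subjects) drops
  s2 <- group_summary(list(f1, f2, f3), threshold = 0.5, group = "g")
  expect_identical(sum(s2$adjacency) / 2, 2)
  expect_identical(unname(s2$adjacency["c", "d"]), 0)
})

test_that("threshold t keeps exactly the edges in >= ceiling(t*N) subjects", {
  set.seed(46)
  for (N in 2:5) {
    fs <- lapply(seq_len(N), function(i) {
      a <- matrix(rbinom(25, 1, 0.4), 5, 5)
      a <- 1 * ((a + t(a)) > 0); diag(a) <- 0
      fcn(a, letters[1:5])
    })
    counts <- Reduce(`+`, lapply(fs, `[[`, "adjacency"))
    for (t in c(0.2, 0.4, 0.7, 1)) {
      s <- group_summary(fs, threshold = t, group = "g")
      manual <- 1 * (counts >= ceiling(t * N)); diag(manual) <- 0
      expect_equal(unname(s$adjacency), unname(manual))
    }
  }
})

test_that("raising the threshold never adds edges; subject order is moot", {
  set.seed(47)
  fs <- lapply(1:6, function(i) {
    a <- matrix(rbinom(36, 1, 0.5), 6, 6)
    a <- 1 * ((a + t(a)) > 0); diag(a) <- 0
    fcn(a, letters[1:6])
  })
  prev <- NULL
  for (t in c(0.1, 0.3, 0.6, 0.9)) {
    s <- group_summary(fs, threshold = t, group = "g")
    if (!is.null(prev)) expect_true(all(s$adjacency <= prev))
    prev <- s$adjacency
  }
  s1 <- group_summary(fs, threshold = 0.4, group = "g")
  s2 <- group_summary(rev(fs), threshold = 0.4, group = "g")
  expect_equal(s1$ratio, s2$ratio)
  expect_error(group_summary(list(), 0.2), "empty")
})

test_that("percentile mode keeps about the requested top fraction", {
  set.seed(48)
  fs <- lapply(1:10, function(i) {
    a <- matrix(rbinom(100, 1, 0.3), 10, 10)
    a <- 1 * ((a + t(a)) > 0); diag(a) <- 0
    fcn(a)
  })
  s <- group_summary(fs, threshold = 0.05, mode = "percentile", group = "g")
  up <- s$ratio[upper.tri(s$ratio)]
  expect_equal(s$threshold, stats::quantile(up[up > 0], 0.95,
                                            names = FALSE))
})

test_that("roi categorization equals the decision table, exhaustively", {
  labels <- sprintf("r%02d", 1:16)
  set.seed(49)
  make_top <- function(rois, group) {
    structure(list(ranking = data.frame(rank = seq_along(rois), roi = rois),
                   group = group, comparison = c("A", "B"),
                   mode = "rank_sum", n_rois = 16L),
              class = "top_roi_list")
  }
  make_prox <- function(near) data.frame(
    roi = labels, distance = runif(16), rank = 1:16,
    near_origin = labels %in% near)
  # randomized membership fixture
  topA <- sample(labels, 6); topB <- sample(labels, 6)
  nearA <- sample(labels, 5); nearB <- sample(labels, 5)
  cm <- categorize_rois(make_top(topA, "A"), make_top(topB, "B"),
                        make_prox(nearA), make_prox(nearB),
                        roi_names = labels)
  for (i in seq_along(labels)) {
    r <- labels[i]
    inA <- r %in% topA; inB <- r %in% topB
    nA <- r %in% nearA; nB <- r %in% nearB
    want <- if (inA && inB && nA && nB) "both"
      else if (inA && inB && nA && !nB) "more_reactive_A"
      else if (inA && inB && !nA && nB) "more_reactive_B"
      else if (inA && !inB) "only_A"
      else if (!inA && inB) "only_B"
      else "none"
    expect_identical(cm$categories$category[cm$categories$roi == r], want)
  }
  expect_identical(nrow(cm$categories), 16L) # one category per ROI
  expect_error(categorize_rois(make_top(topA, "A"), make_top(topB, "B"),
                               make_prox(nearA)[-1, ], make_prox(nearB),
                               roi_names = labels),
               "inconsistent")
})

test_that("clusters are the categorized ROI plus its direct neighbors", {
  labels <- letters[1:6]
  a <- matrix(0, 6, 6, dimnames = list(labels, labels))
  # star centered on "b"; "f" isolated
  for (x in c("a", "c", "d")) { a["b", x] <- a[x, "b"] <- 1 }
  a["d", "e"] <- a["e", "d"] <- 1
  s <- structure(list(ratio = a, adjacency = a, threshold = 0.2,
                      mode = "absolute", group = "A", roi_labels = labels,
                      n_subjects = 3L),
                 class = "summary_fcn")
  cats <- data.frame(
    roi = labels,
    category = c("none", "only_A", "none", "none", "none", "both"),
    in_top_a = FALSE, in_top_b = FALSE,
    near_origin_a = FALSE, near_origin_b = FALSE)
  cm <- structure(list(categories = cats, groups = c("A", "B")),
                  class = "roi_category_map")
  cl <- extract_clusters(s, cm)
  expect_length(cl, 2L)
  star <- cl[[which(vapply(cl, `[[`, character(1), "roi") == "b")]]
  expect_setequal(star$members, c("b", "a", "c", "d")) # whole star
  lone <- cl[[which(vapply(cl, `[[`, character(1), "roi") == "f")]]
  expect_identical(lone$members, "f") # isolated -> singleton
  expect_identical(vapply(cl, `[[`, character(1), "name"), c("A", "B"))
})
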