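# K-means clustering, island-class selection, WCV trace, k rule, and mask
# extraction.

test_that("well-separated clouds are partitioned exactly", {
  set.seed(2)
  a <- matrix(rnorm(200, 0, 0.1), ncol = 2)
  b <- matrix(rnorm(200, 10, 0.1), ncol = 2)
  lab <- cluster_pixels(rbind(a, b), 2, seed = 5)
  expect_equal(length(unique(lab[1:100])), 1)
  expect_equal(length(unique(lab[101:200])), 1)
  expect_false(lab[1] == lab[101])
})

test_that("clustering is deterministic given the seed", {
  set.seed(3)
  x <- matrix(rnorm(900), ncol = 3)
  l1 <- cluster_pixels(x, 3, seed = 7, restarts = 2)
  l2 <- cluster_pixels(x, 3, seed = 7, restarts = 2)
  expect_identical(l1, l2)
})

test_that("identical feature vectors collapse to one cluster with warning", {
  x <- matrix(1, 50, 3)
  expect_warning(lab <- cluster_pixels(x, 2, seed = 1), "degenerate")
  expect_equal(length(unique(lab)), 1)
  expect_error(cluster_pixels(matrix(rnorm(9), 3, 3), 5, seed = 1),
               "exceeds")
})

test_that("island class is the lowest-mean-intensity cluster", {
  labels <- rep(c(0L, 1L), c(40, 60))
  intens <- c(rep(200, 40), rep(20, 60))
  expect_identical(select_island_class(labels, intens), 1L)
  expect_warning(
    tie <- select_island_class(rep(c(2L, 5L), each = 10), rep(7, 20)),
    "tie")
  expect_identical(tie, 2L)
})

test_that("WCV trace normalizes per feature and matches a loop oracle", {
  set.seed(5)
  feats <- matrix(rnorm(300), ncol = 3,
                  dimnames = list(NULL, c("mean", "variance", "spread")))
  ks <- 2:6
  labs <- lapply(ks, function(k) sample.int(k, 100, replace = TRUE))
  isl <- vapply(labs, function(l) as.integer(which.min(tabulate(l))),
                integer(1))
  tr <- wcv_total(feats, labs, isl, ks)
  expect_s3_class(tr, "k_selection_trace")
  expect_equal(length(tr$diffs), length(tr$k_values) - 1)
  # min-max normalization attains 0 and 1 per feature
  for (j in 1:3) {
    expect_equal(min(tr$wcv_normalized[, j]), 0)
    expect_equal(max(tr$wcv_normalized[, j]), 1)
  }
  # raw WCV equals population variance over island-class rows
  pvar <- function(v) mean((v - mean(v))^2)
  for (i in seq_along(ks)) {
    sel <- labs[[i]] == isl[i]
    for (j in 1:3)
      expect_equal(unname(tr$wcv_per_feature[i, j]),
                   unname(pvar(feats[sel, j])), tolerance = 1e-10)
  }
  # zero-variance island class gives zero raw WCV
  feats0 <- feats; feats0[labs[[1]] == isl[1], ] <- 3.3
  tr0 <- wcv_total(feats0, labs, isl, ks)
  expect_equal(unname(tr0$wcv_per_feature[1, ]), c(0, 0, 0))
})

test_that("select_k applies the sign-change rule with plateaus and fallback", {
  mk <- function(total, ks = seq(2, length.out = length(total))) {
    structure(list(k_values = ks, wcv_total = total, diffs = diff(total)),
              class = "k_selection_trace")
  }
  # diffs -3, -1, +0.5, +0.5 -> local minimum at k = 4
  expect_equal(as.integer(select_k(mk(c(10, 7, 6, 6.5, 7)))), 4L)
  expect_false(attr(select_k(mk(c(10, 7, 6, 6.5, 7))), "fallback"))
  # monotone decreasing -> argmin fallback at the last k
  s <- select_k(mk(c(10, 8, 6, 5, 4)))
  expect_equal(as.integer(s), 6L)
  expect_true(attr(s, "fallback"))
  # plateau then rise: zero diffs continue the sign; plateau start selected
  expect_equal(as.integer(select_k(mk(c(10, 7, 7, 8)))), 3L)
  # rising from the start only -> fallback to k = 2
  s2 <- select_k(mk(c(1, 2, 3, 4)))
  expect_equal(as.integer(s2), 2L)
  expect_true(attr(s2, "fallback"))
  expect_error(select_k(mk(c(5, 4))), "at least 2")
})

test_that("extract_islands keeps interior blobs and drops specks and rims", {
  valid <- matrix(TRUE, 40, 40)
  lm <- matrix(0L, 40, 40)
  lm[10:29, 10:29] <- 1L          # 400-px blob
  lm[35, 35] <- 1L                # speck
  lm[1:40, 1] <- 1L               # rim-touching stripe
  out <- extract_islands(lm, 1L, valid, min_island_area = 0.5,
                         pixel_size = 0.1, cleanup_radius = 2L)
  expect_equal(length(out$island_masks), 1)
  expect_gte(sum(out$island_masks[[1]] & (lm == 1L)), 390)
  # boundary pixels are island pixels 4-adjacent to the exterior
  b <- out$boundaries[[1]]
  expect_true(all(out$island_masks[[1]][b]))
  inner <- EBImage::erode(out$island_masks[[1]] * 1,
                          EBImage::makeBrush(3, "diamond")) > 0.5
  expect_equal(b, out$island_masks[[1]] & !inner)
  # empty class -> empty result
  expect_length(extract_islands(lm, 9L, valid)$island_masks, 0)
})
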