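# Local image-moment features: closed forms, brute-force window oracle,
# standardization contract, equivariances.

test_that("constant and point-mass windows match closed forms", {
  fs <- local_moment_features(matrix(5, 7, 7), window = 3)
  expect_equal(fs$mean_map[4, 4], 5)
  expect_equal(fs$variance_map[4, 4], 0)
  # sum(x^2) = sum(y^2) = 6 over offsets {-1,0,1}^2, normalized by 9c/c
  expect_equal(fs$spread_map[4, 4], 4 / 3)

  img <- matrix(0, 7, 7); img[4, 4] <- 3
  fs2 <- local_moment_features(img, window = 3)
  expect_equal(fs2$mean_map[4, 4], 3 / 9)
  expect_equal(fs2$variance_map[4, 4], 8 * 9 / 81)
  expect_equal(fs2$spread_map[4, 4], 0)   # point mass at its own centroid
})

test_that("features agree with the loop oracle on random images", {
  set.seed(7)
  for (rep in 1:5) {
    img <- matrix(runif(16 * 16, 0, 50), 16, 16)
    fs <- local_moment_features(img, window = 3)
    for (r in c(2, 7, 15)) for (c in c(2, 9, 15)) {
      o <- moment_oracle(img, r, c)
      expect_equal(fs$mean_map[r, c], o[["mean"]], tolerance = 1e-10)
      expect_equal(fs$variance_map[r, c], o[["variance"]], tolerance = 1e-10)
      expect_equal(fs$spread_map[r, c], o[["spread"]], tolerance = 1e-10)
    }
  }
})

test_that("windows overlapping the ROI edge are excluded via valid_mask", {
  roi <- matrix(TRUE, 8, 8); roi[1:2, ] <- FALSE
  fs <- local_moment_features(matrix(runif(64), 8, 8), window = 3, roi = roi)
  expect_false(any(fs$valid_mask[1:3, ]))   # rows 1-3 lack a full window
  expect_true(all(fs$valid_mask[4:7, 2:7]))
  expect_true(all(is.na(fs$mean_map[!fs$valid_mask])))
})

test_that("feature maps are translation-equivariant in the interior", {
  set.seed(11)
  img <- matrix(runif(144), 12, 12)
  sh <- rbind(img[3:12, ], matrix(0, 2, 12))  # shift up by 2
  a <- local_moment_features(img, 3)
  b <- local_moment_features(sh, 3)
  expect_equal(b$mean_map[2:8, 2:11], a$mean_map[4:10, 2:11])
  expect_equal(b$spread_map[2:8, 2:11], a$spread_map[4:10, 2:11])
})

test_that("invalid windows and degenerate ROIs error", {
  expect_error(local_moment_features(matrix(1, 5, 5), window = 4), "odd")
  roi <- matrix(FALSE, 5, 5); roi[3, 3] <- TRUE
  expect_error(local_moment_features(matrix(1, 5, 5), 3, roi), "full window")
})

test_that("standardization yields mean 0 / sd 1 and handles degeneracy", {
  set.seed(3)
  fs <- local_moment_features(matrix(runif(100, 0, 9), 10, 10), 3)
  z <- standardize_features(fs)
  expect_lt(max(abs(colMeans(z))), 1e-9)
  expect_equal(unname(apply(z, 2, sd)), rep(1, 3), tolerance = 1e-9)

  w <- capture_warnings(zc <- standardize_features(
    local_moment_features(matrix(4, 10, 10), 3)))
  expect_true(all(grepl("zero variance", w)))
  expect_true(all(zc == 0))
})

test_that("standardized mean/variance are invariant to affine rescale", {
  set.seed(5)
  img <- matrix(runif(100, 1, 20), 10, 10)
  z1 <- standardize_features(local_moment_features(img, 3))
  z2 <- standardize_features(local_moment_features(3.7 * img + 11, 3))
  expect_equal(z1[, "mean"], z2[, "mean"], tolerance = 1e-8)
  expect_equal(z1[, "variance"], z2[, "variance"], tolerance = 1e-8)
  # spread is intensity-weighted, so only pure scaling leaves it unchanged
  z3 <- standardize_features(local_moment_features(3.7 * img, 3))
  expect_equal(z1[, "spread"], z3[, "spread"], tolerance = 1e-8)
})
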