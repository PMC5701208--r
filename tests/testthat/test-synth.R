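# Synthetic-image generator: geometry, focus placement laws, rendering,
# and determinism.

test_that("island shape sampling respects count, area, and set relations", {
  p <- small_synth(1)
  set.seed(10)
  expect_length(sample_island_shapes(synth_params(n_islands = 0L)), 0)
  set.seed(10)
  nuc <- porefree:::.nucleus_mask(p)
  masks <- sample_island_shapes(p, nuc)
  expect_length(masks, p$n_islands)
  target_px <- p$island_area_range / p$pixel_size^2
  for (m in masks) {
    expect_gte(sum(m), target_px[1] * 0.9)
    expect_lte(sum(m), target_px[2] * 1.1)
    expect_true(all(nuc[m]))       # contained in the nucleus
  }
  if (length(masks) > 1)
    expect_equal(sum(masks[[1]] & masks[[2]]), 0)  # disjoint
  # impossible request errors
  tiny <- synth_params(image_shape = c(64L, 64L), nucleus_radius = 1.5,
                       n_islands = 5L, island_area_range = c(6, 7))
  set.seed(3)
  expect_error(sample_island_shapes(tiny), "disjoint")
})

test_that("uniform placement is CSR over the mask (chi-square on distance)", {
  n <- 41L; ctr <- 21
  x <- matrix(rep(1:n, n), n, n); y <- t(x)
  disc <- (x - ctr)^2 + (y - ctr)^2 <= 18^2
  set.seed(12)
  # density chosen so ~10,000 points land in the disc
  pts <- place_foci(disc, 10000 / (sum(disc) * 0.01), pixel_size = 0.1)
  expect_gt(nrow(pts), 5000)
  pr <- round(pts[, 1]) + 1; pc <- round(pts[, 2]) + 1
  expect_true(all(disc[cbind(pr, pc)]))
  f <- distance_field(disc)
  b <- ceiling(f[cbind(pr, pc)] - 1e-12)
  pc_bins <- tabulate(ceiling(f[disc] - 1e-12))
  obs <- tabulate(b, nbins = length(pc_bins))
  expected <- nrow(pts) * pc_bins / sum(pc_bins)
  keep <- expected >= 5
  stat <- sum((obs[keep] - expected[keep])^2 / expected[keep])
  expect_gt(pchisq(stat, sum(keep) - 1, lower.tail = FALSE), 0.01)
})

test_that("boundary-biased placement sits deeper than uniform", {
  n <- 41L; ctr <- 21
  x <- matrix(rep(1:n, n), n, n); y <- t(x)
  disc <- (x - ctr)^2 + (y - ctr)^2 <= 18^2
  f <- distance_field(disc)
  set.seed(14)
  dens <- 3000 / (sum(disc) * 0.01)
  uni <- place_foci(disc, dens, 0.1, mode = "uniform")
  bia <- place_foci(disc, dens, 0.1, mode = "boundary_biased",
                    bias_strength = 3)
  d_of <- function(p) f[cbind(round(p[, 1]) + 1, round(p[, 2]) + 1)]
  tt <- t.test(d_of(bia), d_of(uni), alternative = "greater")
  expect_lt(tt$p.value, 1e-6)
})

test_that("hard-core placement enforces the minimum distance", {
  m <- matrix(TRUE, 60, 60)
  set.seed(15)
  pts <- place_foci(m, 2.5, 0.1, min_dist = 0.5)
  expect_gt(nrow(pts), 10)
  d <- as.matrix(dist(pts))
  diag(d) <- Inf
  expect_gte(min(d), 0.5 / 0.1 - 1.5)  # centers on pixels, +-0.5 jitter
})

test_that("density 0 gives no foci and empty masks give empty output", {
  m <- matrix(TRUE, 20, 20)
  expect_equal(nrow(place_foci(m, 0, 0.1)), 0)
  expect_equal(nrow(place_foci(matrix(FALSE, 5, 5), 10, 0.1)), 0)
})

test_that("rendering honours zero-signal and PSF-symmetry cases", {
  p <- synth_params(image_shape = c(32L, 32L), photon_scale = 0,
                    bg_offset = 0, read_noise_sd = 0)
  set.seed(1)
  img <- render_channel(cbind(row = 15.0, col = 15.0), p)
  expect_true(all(img == 0))
  p2 <- synth_params(image_shape = c(33L, 33L), photon_scale = 1e5,
                     halo_fraction = 0, bg_offset = 0, read_noise_sd = 0)
  set.seed(2)
  img2 <- render_channel(cbind(row = 16.0, col = 16.0), p2)
  expect_equal(arrayInd(which.max(img2), dim(img2)), cbind(17L, 17L))
})

test_that("generator output is bit-identical for a fixed seed", {
  p <- small_synth(99)
  a <- synth_sample(p)
  b <- synth_sample(p)
  expect_identical(a$sample$channel_a, b$sample$channel_a)
  expect_identical(a$sample$channel_b, b$sample$channel_b)
  expect_identical(a$truth$island_foci, b$truth$island_foci)
})

test_that("islands contain zero channel-A foci by construction", {
  ss <- synth_sample(small_synth(5))
  union <- Reduce(`|`, ss$truth$island_masks)
  pr <- round(ss$truth$pore_rich_foci[, 1]) + 1
  pc <- round(ss$truth$pore_rich_foci[, 2]) + 1
  expect_equal(sum(union[cbind(pr, pc)]), 0)
  # island channel-B foci lie inside their island
  for (i in seq_along(ss$truth$island_foci)) {
    fo <- ss$truth$island_foci[[i]]
    if (nrow(fo) == 0) next
    expect_true(all(ss$truth$island_masks[[i]][
      cbind(round(fo[, 1]) + 1, round(fo[, 2]) + 1)]))
  }
})
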