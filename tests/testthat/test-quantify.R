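# Island metrics, distance fields, distance profiles, aggregation, and the
# proximal/distal split.

test_that("island metrics arithmetic", {
  m <- square_island(32)  # 1024 px
  rec <- island_metrics(m, n_foci = 12, pixel_size = 0.1)
  expect_equal(rec$area_px, 1024)
  expect_equal(rec$area_um2, 1024 * 0.01)
  expect_equal(rec$frequency, 12 / 10.24)
  expect_equal(island_metrics(m, 0, 0.1)$frequency, 0)
  # whole-ROI density-mode scale: 256 foci over 100 um^2 -> 2.56 foci/um^2
  big <- matrix(TRUE, 101, 100); big[1, 1] <- FALSE
  big_rec <- island_metrics(big, 256, pixel_size = sqrt(100 / sum(big)))
  expect_equal(big_rec$frequency, 2.56, tolerance = 1e-12)
})

test_that("3x3 island distance field is rim 1 / center 2", {
  m <- square_island(3, 9)
  f <- distance_field(m)
  vals <- f[m]
  expect_equal(sort(unique(vals)), c(1, 2))
  expect_equal(sum(vals == 1), 8)
  expect_equal(sum(vals == 2), 1)
  # single-pixel island
  s <- matrix(FALSE, 5, 5); s[3, 3] <- TRUE
  expect_equal(distance_field(s)[3, 3], 1)
})

test_that("distance field equals the brute-force oracle on random masks", {
  set.seed(13)
  for (rep in 1:15) {
    m <- matrix(runif(24 * 24) < 0.5, 24, 24)
    if (!any(m) || !any(!m)) next
    f <- distance_field(m)
    o <- edt_oracle(m)
    expect_equal(f[m], o[m], tolerance = 1e-12)
  }
})

test_that("distance profile bins foci by the field at their pixel", {
  m <- square_island(3, 9)
  f <- distance_field(m)
  center <- which(f == 2, arr.ind = TRUE)
  prof <- distance_profile(cbind(row = center[1] - 1, col = center[2] - 1), f)
  expect_equal(prof$pixel_counts, c(8, 1))
  expect_equal(prof$focus_counts, c(0, 1))
  expect_equal(prof$raw_frequency, c(0, 1))

  empty <- distance_profile(matrix(numeric(0), 0, 2), f)
  expect_equal(sum(empty$focus_counts), 0)
  expect_error(distance_profile(cbind(row = 0, col = 0), f), "outside")
})

test_that("focus counts are conserved through profiling", {
  set.seed(21)
  m <- square_island(15, 25)
  f <- distance_field(m)
  pix <- which(m)
  n <- 40
  idx <- sample(pix, n, replace = TRUE)
  rc <- arrayInd(idx, dim(m))
  prof <- distance_profile(cbind(rc[, 1] - 1, rc[, 2] - 1), f)
  expect_equal(sum(prof$focus_counts), n)
  expect_equal(sum(prof$pixel_counts), sum(m))
})

test_that("aggregation averages bin-wise and normalizes to 1", {
  m1 <- square_island(9, 15); m2 <- square_island(15, 21)
  f1 <- distance_field(m1); f2 <- distance_field(m2)
  set.seed(5)
  mk <- function(m, f, n) {
    idx <- sample(which(m), n, replace = TRUE)
    rc <- arrayInd(idx, dim(m))
    distance_profile(cbind(rc[, 1] - 1, rc[, 2] - 1), f)
  }
  p1 <- mk(m1, f1, 7); p2 <- mk(m2, f2, 12)
  agg <- aggregate_profiles(list(p1, p2))
  expect_equal(sum(agg$normalized_frequency), 1, tolerance = 1e-9)
  # bins beyond island 1's max distance are averaged over island 2 only
  nb1 <- length(p1$focus_counts)
  expect_equal(agg$raw_frequency[nb1 + 1],
               p2$raw_frequency[nb1 + 1])
  # single profile: own frequencies rescaled to sum 1
  a1 <- aggregate_profiles(list(p1))
  expect_equal(a1$normalized_frequency,
               p1$raw_frequency / sum(p1$raw_frequency))
  # duplicated profile: averaging is idempotent
  a2 <- aggregate_profiles(list(p1, p1))
  expect_equal(a2$normalized_frequency, a1$normalized_frequency)
  # all-empty profiles flagged
  p0 <- distance_profile(matrix(numeric(0), 0, 2), f1)
  expect_true(attr(aggregate_profiles(list(p0)), "flagged"))
})

test_that("proximal/distal split follows the floor rule and partitions", {
  mk_prof <- function(nb) structure(
    list(bin_lo = 0:(nb - 1), bin_hi = 1:nb,
         focus_counts = rep(1, nb), pixel_counts = rep(10, nb),
         raw_frequency = rep(0.1, nb), distance_bin = 1,
         kind = "observed", n_islands = 1L),
    class = "distance_profile")
  s10 <- split_proximal_distal(mk_prof(10), 0.5)
  expect_equal(s10$proximal, 1:5)
  expect_equal(s10$distal, 6:10)
  s3 <- split_proximal_distal(mk_prof(3), 0.5)
  expect_equal(s3$proximal, 1L)
  expect_equal(s3$distal, 2:3)
  for (nb in c(2, 5, 9)) for (fr in c(0.2, 0.5, 0.8)) {
    s <- split_proximal_distal(mk_prof(nb), fr)
    expect_equal(sort(c(s$proximal, s$distal)), seq_len(nb))
    expect_gt(length(s$proximal), 0)
    expect_gt(length(s$distal), 0)
  }
  s1 <- split_proximal_distal(mk_prof(1), 0.5)
  expect_length(s1$distal, 0)
  expect_true(attr(s1, "flagged"))
})
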