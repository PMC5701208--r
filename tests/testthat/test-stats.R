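# Brunner-Munzel test and the condition/profile comparison wrappers.

test_that("symmetric samples give p_hat 0.5 and p = 1", {
  r <- brunner_munzel(c(1, 2), c(1, 2))
  expect_equal(r$p_hat, 0.5)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_equal(r$significance_label, "N.S.")
})

test_that("p_hat matches the exhaustive pair oracle", {
  r <- brunner_munzel(c(1, 2, 3, 4), c(2, 3, 4, 5))
  expect_equal(r$p_hat, 0.71875)  # 10 wins + 3 ties * 0.5 over 16 pairs
  set.seed(17)
  for (rep in 1:50) {
    x <- rnorm(sample(4:12, 1)); y <- rnorm(sample(4:12, 1), mean = runif(1))
    r <- brunner_munzel(x, y)
    expect_equal(r$p_hat, phat_oracle(x, y), tolerance = 1e-12)
    expect_true(is.finite(r$statistic))
  }
})

test_that("p_hat is antisymmetric and ranks are transform-invariant", {
  set.seed(23)
  for (rep in 1:10) {
    x <- rnorm(8); y <- rnorm(10, 0.5)
    expect_equal(brunner_munzel(x, y)$p_hat + brunner_munzel(y, x)$p_hat, 1)
    a <- brunner_munzel(x, y)
    b <- brunner_munzel(exp(x), exp(y))  # strictly monotone transform
    expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
    expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
  }
})

test_that("degenerate and undersized samples error", {
  expect_error(brunner_munzel(c(1, 1, 1), c(1, 1, 1)), "DEGENERATE")
  expect_error(brunner_munzel(1, c(1, 2)), "at least 2")
})

test_that("type-I error is calibrated at alpha 0.05", {
  set.seed(31)
  rejections <- 0L; n_rep <- 200L
  for (i in seq_len(n_rep)) {
    x <- rnorm(30); y <- rnorm(30)
    if (brunner_munzel(x, y)$p_value < 0.05) rejections <- rejections + 1L
  }
  rate <- rejections / n_rep
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("a 1-sd shift at n = 50/50 is detected with high power", {
  set.seed(37)
  rej <- 0L
  for (i in 1:50) {
    if (brunner_munzel(rnorm(50), rnorm(50, 1))$p_value < 0.05) rej <- rej + 1L
  }
  expect_gt(rej / 50, 0.9)
})

test_that("compare_conditions tests island measures per condition pair", {
  set.seed(41)
  rec <- data.frame(
    condition = rep(c("aphidicolin_6_NUP107", "roscovitine_6_NUP107"),
                    each = 30),
    area_um2 = c(rlnorm(30, 2, 0.3), rlnorm(30, 2.6, 0.3)),
    frequency = c(rnorm(30, 1, 0.2), rnorm(30, 1, 0.2)))
  out <- compare_conditions(rec, "area_um2")
  expect_equal(nrow(out), 1)
  expect_lt(out$p_value, 0.001)
  expect_equal(out$label, "***")
  out2 <- compare_conditions(rec, "frequency")
  expect_gt(out2$p_value, 0.001)
  # identical groups: N.S.
  rec$frequency <- rep(seq_len(30), 2)
  out3 <- compare_conditions(rec, "frequency")
  expect_equal(out3$p_value, 1)
  expect_equal(out3$label, "N.S.")
})

test_that("compare_profiles flags no difference for identical shares", {
  masks <- lapply(c(9, 11, 13, 15, 17, 19), square_island)
  fields <- lapply(masks, distance_field)
  profs <- list(); sims <- list()
  set.seed(43)
  for (i in seq_along(masks)) {
    idx <- sample(which(masks[[i]]), 6, replace = TRUE)
    rc <- arrayInd(idx, dim(masks[[i]]))
    profs[[i]] <- distance_profile(cbind(rc[, 1] - 1, rc[, 2] - 1),
                                   fields[[i]])
    sims[[i]] <- profs[[i]]$focus_counts  # simulated identical to observed
  }
  out <- compare_profiles(profs, sims)
  expect_equal(nrow(out), 2)
  expect_true(all(out$region == c("proximal", "distal")))
  expect_true(all(is.na(out$label) | out$label == "N.S."))
})
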