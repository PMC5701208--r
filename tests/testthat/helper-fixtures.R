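# Shared fixtures: small deterministic images and generic helpers.

# brute-force local moment features for one pixel (loop oracle)
moment_oracle <- function(img, r, c, h = 1L) {
  vals <- c(); xr <- c(); yc <- c()
  for (dr in -h:h) for (dc in -h:h) {
    vals <- c(vals, img[r + dr, c + dc]); xr <- c(xr, dr); yc <- c(yc, dc)
  }
  m <- mean(vals)
  v <- mean((vals - m)^2)
  s <- if (sum(vals) == 0) 0 else {
    xb <- sum(vals * xr) / sum(vals); yb <- sum(vals * yc) / sum(vals)
    sum(vals * ((xr - xb)^2 + (yc - yb)^2)) / sum(vals)
  }
  c(mean = m, variance = v, spread = s)
}

# exhaustive Otsu: maximize between-class variance over all 256 thresholds
otsu_oracle <- function(h) {
  n <- sum(h); lv <- 0:255
  best_t <- NA_integer_; best_v <- -Inf
  for (t in 0:255) {
    w0 <- sum(h[1:(t + 1)]) / n; w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(h[1:(t + 1)] * lv[1:(t + 1)]) / sum(h[1:(t + 1)])
    mu1 <- sum(h[(t + 2):256] * lv[(t + 2):256]) / sum(h[(t + 2):256])
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best_v + 1e-12) { best_v <- v; best_t <- t }
  }
  best_t
}

# brute-force Euclidean distance transform
edt_oracle <- function(mask) {
  out <- matrix(NA_real_, nrow(mask), ncol(mask))
  bg <- which(!mask, arr.ind = TRUE)
  for (p in which(mask)) {
    rc <- arrayInd(p, dim(mask))
    out[p] <- sqrt(min((bg[, 1] - rc[1])^2 + (bg[, 2] - rc[2])^2))
  }
  out
}

# exhaustive-pair estimate of P(X < Y) + 0.5 P(X = Y)
phat_oracle <- function(x, y) {
  s <- 0
  for (xi in x) for (yi in y) s <- s + (xi < yi) + 0.5 * (xi == yi)
  s / (length(x) * length(y))
}

# greedy one-to-one matching of detected vs true foci within a radius
match_foci <- function(det, truth, r = 1.5) {
  if (nrow(det) == 0 || nrow(truth) == 0)
    return(c(tp = 0, fp = nrow(det), fn = nrow(truth)))
  d <- outer(seq_len(nrow(det)), seq_len(nrow(truth)), function(i, j)
    sqrt((det$row[i] - truth[j, 1])^2 + (det$col[i] - truth[j, 2])^2))
  tp <- 0
  repeat {
    m <- which(d == min(d), arr.ind = TRUE)[1, ]
    if (!is.finite(d[m[1], m[2]]) || d[m[1], m[2]] > r) break
    tp <- tp + 1; d[m[1], ] <- Inf; d[, m[2]] <- Inf
  }
  c(tp = tp, fp = nrow(det) - tp, fn = nrow(truth) - tp)
}

iou <- function(a, b) sum(a & b) / sum(a | b)

# small square island mask centred in a larger frame
square_island <- function(side, frame = side + 6L) {
  m <- matrix(FALSE, frame, frame)
  lo <- (frame - side) %/% 2 + 1L
  m[lo:(lo + side - 1L), lo:(lo + side - 1L)] <- TRUE
  m
}

# a fast small-scale synthetic parameter set for pipeline-level tests
small_synth <- function(seed, ...) {
  synth_params(image_shape = c(220L, 220L), nucleus_radius = 6,
               island_area_range = c(6, 10), seed = seed, ...)
}
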