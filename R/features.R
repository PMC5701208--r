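# Local image-moment texture features: per-pixel mean, variance and
# intensity-weighted second-order central spatial moment over a sliding
# w x w window. These three maps (brightness, contrast, intensity spread)
# are the feature space in which pore-free islands are separable from the
# pore-rich texture.

#' Sum of shifted copies of a matrix over window offsets
#'
#' For each pixel p returns sum over the window W(p) of `weight(offset) *
#' img[p + offset]`. Out-of-image pixels contribute 0.
#' @noRd
.window_sum <- function(img, offsets, weights) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nrow(offsets))) {
    dr <- offsets[i, 1L]; dc <- offsets[i, 2L]
    src_r <- max(1L, 1L + dr):min(nr, nr + dr)
    src_c <- max(1L, 1L + dc):min(nc, nc + dc)
    dst_r <- src_r - dr; dst_c <- src_c - dc
    out[dst_r, dst_c] <- out[dst_r, dst_c] + weights[i] * img[src_r, src_c]
  }
  out
}

#' Compute local image-moment features
#'
#' For every pixel whose full `window` x `window` neighbourhood lies inside
#' the region of interest, computes three local statistics of the intensity
#' image over that neighbourhood:
#' \describe{
#'   \item{mean_map}{window mean intensity (brightness).}
#'   \item{variance_map}{population variance of intensity (contrast).}
#'   \item{spread_map}{trace of the intensity-normalized second-order central
#'     spatial moment matrix about the intensity-weighted centroid of the
#'     window, in px^2 (spatial spread of intensity). Defined as 0 where the
#'     window intensity sum is 0.}
#' }
#'
#' @param image numeric matrix of non-negative intensities.
#' @param window odd integer window side, >= 3.
#' @param roi logical matrix, same shape; pixels outside are ignored. Default
#'   all-`TRUE`.
#' @return object of class `feature_stack`: list with `mean_map`,
#'   `variance_map`, `spread_map` (matrices, `NA` outside `valid_mask`),
#'   `valid_mask` (logical matrix: full window inside the ROI) and `window`.
#' @examples
#' fs <- local_moment_features(matrix(runif(64), 8, 8), window = 3)
#' range(fs$variance_map[fs$valid_mask])
#' @export
local_moment_features <- function(image, window = 3L, roi = NULL) {
  stopifnot(is.matrix(image), is.numeric(image))
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("`window` must be an odd integer >= 3")
  if (is.null(roi)) roi <- matrix(TRUE, nrow(image), ncol(image))
  stopifnot(identical(dim(roi), dim(image)))

  h <- (window - 1L) %/% 2L
  off <- as.matrix(expand.grid(dr = -h:h, dc = -h:h))
  n_win <- nrow(off)

  ones <- rep(1, n_win)
  roi_n <- .window_sum(roi * 1, off, ones)
  valid <- roi_n > n_win - 0.5   # every window pixel inside ROI and image
  if (!any(valid)) stop("no pixel has a full window inside the ROI")

  s0  <- .window_sum(image, off, ones)
  s0sq <- .window_sum(image^2, off, ones)
  s1r <- .window_sum(image, off, off[, "dr"])
  s1c <- .window_sum(image, off, off[, "dc"])
  s2  <- .window_sum(image, off, off[, "dr"]^2 + off[, "dc"]^2)

  mean_map <- s0 / n_win
  variance_map <- pmax(s0sq / n_win - mean_map^2, 0)
  spread_map <- matrix(0, nrow(image), ncol(image))
  pos <- s0 > 0
  spread_map[pos] <- pmax(
    s2[pos] / s0[pos] - (s1r[pos] / s0[pos])^2 - (s1c[pos] / s0[pos])^2, 0)

  mean_map[!valid] <- NA_real_
  variance_map[!valid] <- NA_real_
  spread_map[!valid] <- NA_real_

  structure(list(mean_map = mean_map, variance_map = variance_map,
                 spread_map = spread_map, valid_mask = valid,
                 window = window),
            class = "feature_stack")
}

#' Standardize a feature stack for clustering
#'
#' z-scores each of the three feature maps over the valid pixels (mean 0,
#' sd 1). The three features carry incommensurate units (intensity,
#' intensity^2, px^2) and K-means is scale-sensitive, so clustering always
#' runs on the standardized stack. A zero-variance feature maps to all-zeros
#' with a warning.
#'
#' @param stack a `feature_stack` from [local_moment_features()].
#' @return matrix with one row per valid pixel and columns
#'   `mean`, `variance`, `spread`, plus attributes `valid_mask` and `dim`.
#' @export
standardize_features <- function(stack) {
  stopifnot(inherits(stack, "feature_stack"))
  v <- stack$valid_mask
  if (sum(v) < 2L) stop("need at least 2 valid pixels to standardize")
  feats <- cbind(mean = stack$mean_map[v],
                 variance = stack$variance_map[v],
                 spread = stack$spread_map[v])
  for (j in seq_len(ncol(feats))) {
    s <- stats::sd(feats[, j])
    if (s < .Machine$double.eps^0.5) {
      warning("feature '", colnames(feats)[j],
              "' has zero variance; standardized to all-zeros")
      feats[, j] <- 0
    } else {
      feats[, j] <- (feats[, j] - mean(feats[, j])) / s
    }
  }
  attr(feats, "valid_mask") <- v
  attr(feats, "img_dim") <- dim(stack$mean_map)
  feats
}
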