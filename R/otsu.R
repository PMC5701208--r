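# Otsu thresholding on an explicit 256-bin histogram. Implemented from the
# cumulative-moment recurrences so the tie-break (smallest maximizing t) and
# the class convention (background <= t, foreground > t) are fixed exactly.

#' Otsu threshold of a 256-bin histogram
#'
#' Returns the threshold t* in 0..255 maximizing the between-class variance
#' \eqn{\omega_0 \omega_1 (\mu_0 - \mu_1)^2} for the split into classes
#' {values <= t} and {values > t}. Ties are broken toward the smallest t.
#'
#' @param histogram numeric vector of 256 non-negative counts for values
#'   0..255.
#' @return integer threshold t*; foreground is `value > t*`.
#' @examples
#' h <- numeric(256); h[c(11, 201)] <- 50  # values 10 and 200
#' otsu_threshold(h)  # 10: any split between the two modes is optimal
#' @export
otsu_threshold <- function(histogram) {
  stopifnot(is.numeric(histogram), length(histogram) == 256L,
            all(histogram >= 0))
  if (sum(histogram > 0) < 2L)
    stop("histogram has fewer than 2 nonzero bins; nothing to separate")
  levels <- 0:255
  n <- sum(histogram)
  w0 <- cumsum(histogram) / n              # P(value <= t), t = 0..255
  m0 <- cumsum(histogram * levels) / n     # partial first moment
  mu_t <- m0[256L]
  w1 <- 1 - w0
  # between-class variance; undefined (0/0) where a class is empty
  bcv <- (mu_t * w0 - m0)^2 / (w0 * w1)
  bcv[!is.finite(bcv)] <- -Inf
  as.integer(levels[which.max(bcv)])       # which.max: first (smallest) tie
}
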