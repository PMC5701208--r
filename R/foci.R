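# Single-Nup focus detection. The counterstain is translated into mean
# curvature (foci are sharp caps: strongly negative H at the apex, with
# noise and slopes suppressed by the gradient terms), the negated curvature
# is rescaled to 8 bits over the evaluation region, Otsu's threshold is
# applied to the in-region histogram, and foreground 8-connected components
# within an area band become foci.

#' Detect single-Nup foci
#'
#' In `mode = "islands"` the evaluation region is the union of the
#' recognized pore-free island masks (the islands are the initial region of
#' detection; quantization limits and the Otsu histogram are taken over
#' in-region pixels only). In `mode = "roi"` the same procedure runs over
#' the nucleus ROI eroded by the curvature-kernel radius (rim derivative
#' artifacts would otherwise dominate the 8-bit rescaling); this mode
#' supports whole-nucleus NPC-density estimation.
#'
#' @param channel_b counterstain intensity matrix.
#' @param island_masks list of logical island masks (islands mode).
#' @param nucleus_mask logical nucleus ROI (roi mode).
#' @param cfg a [run_config()].
#' @param mode `"islands"` or `"roi"`.
#' @return object of class `foci_set`: list with `foci` (data.frame:
#'   `row`, `col` 0-based intensity-weighted centroid, `area` px,
#'   `island_id` or `NA`, `peak_intensity`), `threshold_used` (8-bit, `NA`
#'   if nothing to threshold), `mode`, and `eval_area_px` (pixels of the
#'   evaluation region, the denominator for density estimates).
#' @export
detect_foci <- function(channel_b, island_masks = list(),
                        nucleus_mask = NULL, cfg = run_config(),
                        mode = c("islands", "roi")) {
  mode <- match.arg(mode)
  shape <- dim(channel_b)
  if (mode == "islands") {
    region <- Reduce(`|`, island_masks, matrix(FALSE, shape[1L], shape[2L]))
  } else {
    stopifnot(!is.null(nucleus_mask))
    r <- max(3L, ceiling(4 * cfg$curvature_sigma))
    region <- EBImage::erode(nucleus_mask * 1,
                             EBImage::makeBrush(2L * r + 1L, "disc")) > 0.5
  }
  empty <- data.frame(row = numeric(0), col = numeric(0), area = integer(0),
                      island_id = integer(0), peak_intensity = numeric(0))
  out <- function(foci, thr) structure(
    list(foci = foci, threshold_used = thr, mode = mode,
         eval_area_px = sum(region)),
    class = "foci_set")
  if (!any(region)) return(out(empty, NA_integer_))

  # curvature of the raw-count surface is dominated by its gradient terms
  # (they grow with the square of the intensity scale), so the surface is
  # evaluated on the image affinely rescaled to unit range: slopes are then
  # small, the gradient terms are gentle, and peaks carry strongly negative
  # curvature. This also makes detection exactly invariant under affine
  # intensity rescaling of the input.
  rng <- range(channel_b)
  norm_b <- if (diff(rng) > 0) (channel_b - rng[1L]) / diff(rng)
            else channel_b * 0
  h <- mean_curvature(norm_b, cfg$curvature_sigma)
  q <- withCallingHandlers(
    regulate_to_8bit(h, region),
    warning = function(w) invokeRestart("muffleWarning"))
  hist256 <- tabulate(q[region] + 1L, nbins = 256L)
  if (sum(hist256 > 0) < 2L) return(out(empty, NA_integer_))
  thr <- otsu_threshold(hist256)
  fg <- !is.na(q) & q > thr
  lab <- .label8(fg)
  n_comp <- max(lab)
  if (n_comp == 0L) return(out(empty, thr))

  rows <- list()
  for (i in seq_len(n_comp)) {
    comp_idx <- which(lab == i)
    a <- length(comp_idx)
    if (a < cfg$min_focus_area || a > cfg$max_focus_area) next
    rc <- arrayInd(comp_idx, shape)
    w <- channel_b[comp_idx]
    if (sum(w) <= 0) w <- rep(1, a)
    cen_r <- sum((rc[, 1L] - 1) * w) / sum(w)
    cen_c <- sum((rc[, 2L] - 1) * w) / sum(w)
    isl <- NA_integer_
    pr <- as.integer(round(cen_r)) + 1L
    pc <- as.integer(round(cen_c)) + 1L
    if (mode == "islands") {
      for (j in seq_along(island_masks))
        if (island_masks[[j]][pr, pc]) { isl <- j; break }
      if (is.na(isl)) next   # centroid drifted outside every island
    }
    rows[[length(rows) + 1L]] <- data.frame(
      row = cen_r, col = cen_c, area = a, island_id = isl,
      peak_intensity = max(channel_b[comp_idx]))
  }
  foci <- if (length(rows)) do.call(rbind, rows) else empty
  out(foci, thr)
}

#' Whole-ROI focus density
#'
#' Convenience wrapper for the NPC-density validation: detects foci over
#' the (eroded) nucleus ROI and returns the count divided by the evaluated
#' area in um^2.
#'
#' @param channel intensity matrix.
#' @param nucleus_mask logical ROI.
#' @param pixel_size um/px.
#' @param cfg a [run_config()].
#' @return density in foci per um^2.
#' @export
focus_density <- function(channel, nucleus_mask, pixel_size,
                          cfg = run_config()) {
  fs <- detect_foci(channel, nucleus_mask = nucleus_mask, cfg = cfg,
                    mode = "roi")
  nrow(fs$foci) / (fs$eval_area_px * pixel_size^2)
}
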