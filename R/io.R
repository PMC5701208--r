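# Sample IO and automated QC. Images are single-plane grayscale 8/16-bit
# TIFFs; the nucleus ROI is a binary mask TIFF (0/1 or 0/255). QC replaces
# the visual accept/reject step with thresholded flags for the three
# rejection causes seen in practice: intensity saturation, nucleus
# edge-blurring, and minute pore-free islands.

#' Construct and validate a raw sample
#'
#' @param sample_id identifier.
#' @param condition list: `inhibitor`, `treatment_hours`, `antibody`.
#' @param channel_a,channel_b numeric intensity matrices (pan-NPC stain and
#'   single-Nup counterstain), identical shape.
#' @param nucleus_mask logical matrix, identical shape, >= 1 TRUE pixel.
#' @param pixel_size um per pixel (> 0); the instrument calibration must be
#'   supplied -- there is no meaningful universal default.
#' @param bit_depth 8 or 16 (used for the saturation QC).
#' @return list of class `raw_sample`.
#' @export
new_raw_sample <- function(sample_id, condition, channel_a, channel_b,
                           nucleus_mask, pixel_size, bit_depth = 16L) {
  stopifnot(is.matrix(channel_a), is.matrix(channel_b),
            is.matrix(nucleus_mask))
  if (!identical(dim(channel_a), dim(channel_b)) ||
      !identical(dim(channel_a), dim(nucleus_mask)))
    stop("channel_a, channel_b and nucleus_mask must share one shape")
  if (!isTRUE(pixel_size > 0)) stop("pixel_size must be > 0")
  if (!any(nucleus_mask)) stop("nucleus_mask has no foreground pixel")
  stopifnot(bit_depth %in% c(8L, 16L))
  structure(list(sample_id = sample_id, condition = condition,
                 channel_a = channel_a, channel_b = channel_b,
                 nucleus_mask = nucleus_mask == TRUE,
                 pixel_size = pixel_size, bit_depth = as.integer(bit_depth)),
            class = "raw_sample")
}

#' Read one single-plane grayscale TIFF as an integer matrix
#' @noRd
.read_gray_tiff <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
  if (length(dim(img)) != 2L)
    stop("not a single-plane grayscale image: ", path)
  bits <- attr(img, "bits.per.sample")
  if (is.null(bits)) bits <- if (max(img) > 255) 16L else 8L
  structure(matrix(as.numeric(img), nrow(img), ncol(img)),
            bit_depth = as.integer(bits))
}

#' Load a sample from image files
#'
#' Reads channel TIFFs (and an optional binary mask TIFF) into a validated
#' [new_raw_sample()]. Without a mask file the whole image becomes the ROI,
#' with a warning -- interactive nucleus outlining is replaced by mask-file
#' input throughout this package.
#'
#' @param channel_a_path,channel_b_path grayscale single-plane TIFF paths.
#' @param mask_path binary mask TIFF path, or `NA`/`NULL` for none.
#' @param condition list: `inhibitor`, `treatment_hours`, `antibody`.
#' @param pixel_size um per pixel.
#' @param sample_id identifier (default: channel-A file stem).
#' @return a `raw_sample`.
#' @export
load_sample <- function(channel_a_path, channel_b_path, mask_path = NULL,
                        condition = list(inhibitor = NA, treatment_hours = NA,
                                         antibody = NA),
                        pixel_size, sample_id = NULL) {
  a <- .read_gray_tiff(channel_a_path)
  b <- .read_gray_tiff(channel_b_path)
  if (!identical(dim(a), dim(b)))
    stop("shape mismatch between ", channel_a_path, " (",
         paste(dim(a), collapse = "x"), ") and ", channel_b_path, " (",
         paste(dim(b), collapse = "x"), ")")
  if (is.null(mask_path) || is.na(mask_path) || !nzchar(mask_path)) {
    warning("no nucleus mask for ", channel_a_path,
            "; using the whole image as ROI")
    mask <- matrix(TRUE, nrow(a), ncol(a))
  } else {
    m <- .read_gray_tiff(mask_path)
    if (!identical(dim(m), dim(a)))
      stop("shape mismatch between ", channel_a_path, " and mask ",
           mask_path)
    mask <- m > 0
  }
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(channel_a_path))
  bits <- attr(a, "bit_depth")
  attr(a, "bit_depth") <- NULL
  attr(b, "bit_depth") <- NULL
  new_raw_sample(sample_id = sample_id, condition = condition,
                 channel_a = a, channel_b = b, nucleus_mask = mask,
                 pixel_size = pixel_size, bit_depth = bits)
}

#' Normalized gradient energy at the nucleus edge
#'
#' Mean finite-difference gradient magnitude over the nucleus-mask boundary
#' band of a lightly smoothed copy of the channel (sigma 2 px, suppressing
#' shot noise), divided by the mean in-mask intensity. Well-focused
#' bottom-surface images show a crisp intensity falloff at the nucleus rim;
#' defocus depresses this ratio.
#' @noRd
.blur_metric <- function(channel, nucleus_mask) {
  band <- .boundary4(nucleus_mask) |
    (nucleus_mask & !(EBImage::erode(nucleus_mask * 1,
                                     EBImage::makeBrush(5L, "box")) > 0.5))
  if (!any(band)) return(NA_real_)
  g <- .gauss_kernels(2)$g0
  sm <- .conv_sep(channel, g, g)
  nr <- nrow(sm); nc <- ncol(sm)
  gr <- rbind(sm[2:nr, ] - sm[1:(nr - 1), ], rep(0, nc))
  gc <- cbind(sm[, 2:nc] - sm[, 1:(nc - 1)], rep(0, nr))
  gmag <- sqrt(gr^2 + gc^2)
  denom <- mean(channel[nucleus_mask])
  if (denom <= 0) return(NA_real_)
  mean(gmag[band]) / denom
}

#' Automated QC report for one sample
#'
#' Flags: `SATURATED` (fraction of in-mask channel-A pixels at the dtype
#' maximum above `saturation_fraction_limit`), `EDGE_BLUR` (normalized
#' gradient energy at the nucleus edge below `blur_metric_limit`),
#' `NO_ISLANDS` (no island-class component at all), `MINUTE_ISLANDS`
#' (components existed but all fell below `min_island_area` or touched the
#' rim). `accepted` is `TRUE` iff no flag is raised.
#'
#' @param sample a `raw_sample`.
#' @param seg a `segmentation_result` for the sample (or `NULL` if
#'   segmentation failed, which flags `NO_ISLANDS`).
#' @param cfg a [run_config()].
#' @return one-row data.frame of class `qc_report`.
#' @export
compute_qc <- function(sample, seg, cfg = run_config()) {
  maxv <- 2^sample$bit_depth - 1
  in_mask <- sample$channel_a[sample$nucleus_mask]
  sat <- mean(in_mask >= maxv)
  blur <- .blur_metric(sample$channel_a, sample$nucleus_mask)
  n_pre <- if (is.null(seg)) 0L else seg$n_pre_filter
  n_post <- if (is.null(seg)) 0L else length(seg$island_masks)
  flags <- character(0)
  if (sat > cfg$saturation_fraction_limit) flags <- c(flags, "SATURATED")
  if (is.finite(blur) && blur < cfg$blur_metric_limit)
    flags <- c(flags, "EDGE_BLUR")
  if (n_pre == 0L) flags <- c(flags, "NO_ISLANDS")
  else if (n_post == 0L) flags <- c(flags, "MINUTE_ISLANDS")
  structure(data.frame(sample_id = sample$sample_id,
                       saturation_fraction = sat,
                       blur_metric = blur,
                       n_islands_pre_filter = n_pre,
                       n_islands_post_filter = n_post,
                       flags = paste(flags, collapse = ";"),
                       accepted = length(flags) == 0L,
                       stringsAsFactors = FALSE),
            class = c("qc_report", "data.frame"))
}

#' Write an island label mask as a 16-bit TIFF (island ids as pixel values)
#' @noRd
.write_label_tiff <- function(island_masks, shape, path) {
  lab <- matrix(0, shape[1L], shape[2L])
  for (i in seq_along(island_masks)) lab[island_masks[[i]]] <- i
  tiff::writeTIFF(lab / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write a review overlay PNG: grayscale channel, island boundaries in red,
#' focus centroids in green.
#' @noRd
.write_overlay_png <- function(channel, boundaries, foci, path) {
  g <- channel / max(channel, 1)
  rgb <- array(rep(g, 3L), c(nrow(g), ncol(g), 3L))
  for (b in boundaries) {
    rgb[, , 1L][b] <- 1; rgb[, , 2L][b] <- 0; rgb[, , 3L][b] <- 0
  }
  if (!is.null(foci) && nrow(foci) > 0) {
    pr <- pmin(pmax(as.integer(round(foci$row)) + 1L, 1L), nrow(g))
    pc <- pmin(pmax(as.integer(round(foci$col)) + 1L, 1L), ncol(g))
    idx <- cbind(pr, pc)
    rgb[, , 1L][idx] <- 0; rgb[, , 2L][idx] <- 1; rgb[, , 3L][idx] <- 0
  }
  png::writePNG(rgb, path)
  invisible(path)
}
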