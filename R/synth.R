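# Synthetic two-channel NE bottom-surface images with ground truth.
# Channel A emulates a pan-NPC stain: a dense field of diffraction-limited
# foci over the nucleus with one or more smooth pore-free islands that
# contain no channel-A foci at all (the defining property of the islands).
# Channel B emulates a single-Nup counterstain: sparse foci both inside
# islands (uniform or boundary-biased placement) and in the pore-rich
# region. Rendering: unit point masses split between an in-focus Gaussian
# PSF and a wide out-of-focus halo (widefield imaging always carries
# defocused light), a uniform autofluorescence background, Poisson shot
# noise, Gaussian read noise, quantization.

#' Synthetic-image generator parameters
#'
#' Defaults emulate the imaging regime of a 100x/1.35 objective with a
#' 6.45-um-pixel CCD (0.0645 um/px), a ~0.21-um-FWHM PSF (1.4 px sigma),
#' a pore-rich NPC density of 2.5 foci/um^2 and sparse single-Nup foci.
#'
#' @param image_shape integer c(rows, cols).
#' @param pixel_size um per pixel.
#' @param nucleus_radius nucleus ROI radius, um.
#' @param ne_margin extra radius of the imaged NE surface beyond the ROI,
#'   um; emulates an analysis ROI drawn conservatively inside the flat
#'   bottom surface, so pan-NPC texture runs to the ROI edge.
#' @param n_islands number of pore-free islands.
#' @param island_area_range c(min, max) island area, um^2.
#' @param pore_rich_density channel-A focus density, foci/um^2.
#' @param hard_core_dist minimum pairwise distance between channel-A
#'   pan-NPC foci, um. Mature NPCs are anchored in the lamina mesh and are
#'   distributed more evenly than a Poisson process; the hard core makes
#'   the pore-rich texture confluent as in real pan-NPC staining. Set 0 for
#'   pure CSR. Island channel-B foci are never hard-core constrained.
#' @param island_foci_density channel-B focus density (inside islands and,
#'   at the same rate, in the pore-rich region), foci/um^2.
#' @param placement_mode `"uniform"` (CSR) or `"boundary_biased"`.
#' @param bias_strength logistic steepness of the boundary-distance
#'   acceptance (per px) in biased mode.
#' @param psf_sigma in-focus Gaussian PSF sigma, px.
#' @param photon_scale expected photon count integrated over one focus.
#' @param halo_fraction fraction of each focus's flux emitted as a wide
#'   out-of-focus halo instead of the in-focus PSF.
#' @param halo_sigma Gaussian sigma of the out-of-focus halo, px.
#' @param bg_offset uniform autofluorescence/offset background, expected
#'   counts per pixel (Poisson).
#' @param read_noise_sd Gaussian read noise sd, counts.
#' @param bit_depth 8 or 16.
#' @param seed integer; every random choice of the generator flows from it.
#' @return list of class `synth_params`.
#' @export
synth_params <- function(image_shape = c(320L, 320L), pixel_size = 0.0645,
                         nucleus_radius = 9, ne_margin = 1.0,
                         n_islands = 2L,
                         island_area_range = c(8, 20),
                         pore_rich_density = 2.5, hard_core_dist = 0.3,
                         island_foci_density = 0.4,
                         placement_mode = c("uniform", "boundary_biased"),
                         bias_strength = 1.5, psf_sigma = 1.5,
                         photon_scale = 40000, halo_fraction = 0.6,
                         halo_sigma = 3, bg_offset = 100,
                         read_noise_sd = 3,
                         bit_depth = 16L, seed = 1L) {
  placement_mode <- match.arg(placement_mode)
  stopifnot(pixel_size > 0, nucleus_radius > 0, ne_margin >= 0,
            n_islands >= 0,
            pore_rich_density >= 0, hard_core_dist >= 0,
            island_foci_density >= 0,
            psf_sigma > 0, halo_fraction >= 0, halo_fraction <= 1,
            halo_sigma > 0, bg_offset >= 0, bit_depth %in% c(8L, 16L))
  structure(as.list(environment()), class = "synth_params")
}

#' Slightly perturbed disc geometry for the nucleus: draws the perturbation
#' once and returns a closure rasterizing the region at any radius, so the
#' ROI mask and the larger imaged NE surface share one outline shape.
#' @noRd
.nucleus_geometry <- function(params) {
  nr <- params$image_shape[1L]; nc <- params$image_shape[2L]
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  a <- stats::runif(1, 0, 0.05); ph <- stats::runif(1, 0, 2 * pi)
  rr <- matrix(seq_len(nr), nr, nc) - cr
  cc_m <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - cc
  rho <- sqrt(rr^2 + cc_m^2); th <- atan2(cc_m, rr)
  function(radius_um)
    rho <= radius_um / params$pixel_size * (1 + a * cos(2 * th + ph))
}

#' @noRd
.nucleus_mask <- function(params) .nucleus_geometry(params)(params$nucleus_radius)

#' Rasterize one smooth blob (Fourier-perturbed disc)
#' @noRd
.blob_mask <- function(shape, center, r0_px, amps, phases) {
  rr <- matrix(seq_len(shape[1L]), shape[1L], shape[2L]) - center[1L]
  cc <- matrix(seq_len(shape[2L]), shape[1L], shape[2L], byrow = TRUE) -
    center[2L]
  rho <- sqrt(rr^2 + cc^2); th <- atan2(cc, rr)
  pert <- rep(1, length(th))
  for (m in seq_along(amps))
    pert <- pert + amps[m] * cos((m + 1L) * th + phases[m])
  matrix(rho <= r0_px * pert, shape[1L], shape[2L])
}

#' Sample disjoint smooth island shapes inside the nucleus
#'
#' Islands are random low-order Fourier perturbations of discs, with areas
#' drawn uniformly from `island_area_range` (hit within ~10% after one
#' radius correction), pairwise separated by at least a 2-px gap, and
#' placed fully inside the nucleus away from its rim. Uses the current RNG
#' state; seed via [set.seed()] or let [synth_sample()] manage it.
#'
#' @param params a `synth_params`.
#' @param nucleus_mask logical matrix; default built from `params`.
#' @param max_tries placement attempts per island before giving up.
#' @return list of logical matrices (possibly empty).
#' @export
sample_island_shapes <- function(params, nucleus_mask = NULL,
                                 max_tries = 200L) {
  if (params$n_islands == 0L) return(list())
  if (is.null(nucleus_mask)) nucleus_mask <- .nucleus_mask(params)
  shape <- dim(nucleus_mask)
  # islands are analyzed only when fully surrounded by pore-rich NE: keep
  # them at least ~1 um inside the ROI edge
  marg <- max(2L, round(1.0 / params$pixel_size))
  allowed <- EBImage::erode(nucleus_mask * 1,
                            EBImage::makeBrush(2L * marg + 1L, "disc")) > 0.5
  forbidden <- matrix(FALSE, shape[1L], shape[2L])
  gap_brush <- EBImage::makeBrush(5L, "box")   # >= 2 px gap between islands
  masks <- list()
  for (i in seq_len(params$n_islands)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      target <- stats::runif(1, params$island_area_range[1L],
                             params$island_area_range[2L])
      r0 <- sqrt(target / pi) / params$pixel_size
      amps <- stats::runif(3, 0, 0.12)
      phases <- stats::runif(3, 0, 2 * pi)
      ctr_idx <- sample(which(allowed), 1L)
      ctr <- arrayInd(ctr_idx, shape) + stats::runif(2, -0.5, 0.5)
      m <- .blob_mask(shape, ctr, r0, amps, phases)
      # one-step area correction toward the target
      m <- .blob_mask(shape, ctr, r0 * sqrt((target / params$pixel_size^2) /
                                              max(sum(m), 1L)), amps, phases)
      if (!any(m)) next
      if (any(m & !allowed)) next
      if (any(m & forbidden)) next
      masks[[length(masks) + 1L]] <- m
      forbidden <- forbidden |
        (EBImage::dilate(m * 1, gap_brush) > 0.5)
      placed <- TRUE
      break
    }
    if (!placed)
      stop("could not place ", params$n_islands, " disjoint islands; ",
           "reduce island_area_range or their number")
  }
  masks
}

#' Place foci inside a region
#'
#' Focus count is Poisson(`density` x region area in um^2). In `uniform`
#' mode positions are uniform over the region pixels with subpixel jitter;
#' in `boundary_biased` mode candidate positions are accepted with a
#' logistic probability increasing in the boundary distance,
#' `plogis(bias_strength * (d - d_half))` with `d_half` half the region's
#' maximum boundary distance. Uses the current RNG state.
#'
#' @param region_mask logical matrix.
#' @param density foci per um^2.
#' @param pixel_size um per px.
#' @param mode `"uniform"` or `"boundary_biased"`.
#' @param bias_strength logistic steepness (biased mode).
#' @param min_dist hard-core minimum pairwise distance in um (uniform mode
#'   only); candidates closer than this to an accepted focus are rejected
#'   (dart throwing). 0 disables the constraint.
#' @return numeric matrix with columns `row`, `col`: 0-based subpixel
#'   coordinates, all inside the region (possibly 0 rows).
#' @export
place_foci <- function(region_mask, density, pixel_size,
                       mode = c("uniform", "boundary_biased"),
                       bias_strength = 1.5, min_dist = 0) {
  mode <- match.arg(mode)
  stopifnot(density >= 0, pixel_size > 0, min_dist >= 0)
  empty <- matrix(numeric(0), 0L, 2L, dimnames = list(NULL, c("row", "col")))
  if (!any(region_mask)) return(empty)
  area_um2 <- sum(region_mask) * pixel_size^2
  n <- stats::rpois(1L, density * area_um2)
  if (n == 0L) return(empty)
  pix <- which(region_mask)
  if (mode == "uniform" && min_dist > 0) {
    d_px <- min_dist / pixel_size
    rc_all <- arrayInd(pix, dim(region_mask))
    acc <- matrix(NA_real_, 0L, 2L)
    tries <- 0L
    while (nrow(acc) < n && tries < 50L * n) {
      cand <- rc_all[sample.int(length(pix), 1L), ]
      tries <- tries + 1L
      if (nrow(acc) == 0L ||
          min((acc[, 1L] - cand[1L])^2 + (acc[, 2L] - cand[2L])^2) >=
            d_px^2)
        acc <- rbind(acc, cand)
    }
    n <- nrow(acc)
    if (n == 0L) return(empty)
    return(cbind(row = acc[, 1L] - 1 + stats::runif(n, -0.499, 0.499),
                 col = acc[, 2L] - 1 + stats::runif(n, -0.499, 0.499)))
  }
  if (mode == "uniform") {
    idx <- pix[sample.int(length(pix), n, replace = TRUE)]
  } else {
    df <- distance_field(region_mask)
    d <- df[region_mask]
    d_half <- max(d) / 2
    acc_p <- stats::plogis(bias_strength * (d - d_half))
    idx <- integer(0)
    guard <- 0L
    while (length(idx) < n && guard < 10000L) {
      batch <- sample.int(length(pix), max(4L * n, 64L), replace = TRUE)
      keep <- stats::runif(length(batch)) < acc_p[batch]
      idx <- c(idx, pix[batch[keep]])
      guard <- guard + 1L
    }
    idx <- idx[seq_len(n)]
  }
  rc <- arrayInd(idx, dim(region_mask))
  coords <- cbind(row = rc[, 1L] - 1 + stats::runif(n, -0.499, 0.499),
                  col = rc[, 2L] - 1 + stats::runif(n, -0.499, 0.499))
  coords
}

#' Bilinear splat of unit point masses onto a canvas
#' @noRd
.splat <- function(coords, shape) {
  img <- matrix(0, shape[1L], shape[2L])
  if (is.null(coords) || nrow(coords) == 0L) return(img)
  for (i in seq_len(nrow(coords))) {
    y <- coords[i, 1L]; x <- coords[i, 2L]
    i0 <- floor(y); j0 <- floor(x)
    fy <- y - i0; fx <- x - j0
    for (dd in list(c(0, 0, (1 - fy) * (1 - fx)), c(1, 0, fy * (1 - fx)),
                    c(0, 1, (1 - fy) * fx), c(1, 1, fy * fx))) {
      r <- i0 + dd[1L] + 1L; c <- j0 + dd[2L] + 1L
      if (r >= 1 && r <= shape[1L] && c >= 1 && c <= shape[2L])
        img[r, c] <- img[r, c] + dd[3L]
    }
  }
  img
}

#' Render focus coordinates into a noisy quantized image
#'
#' Each focus contributes `photon_scale` expected photons, split between
#' the in-focus Gaussian PSF (`1 - halo_fraction`) and a wide out-of-focus
#' halo (`halo_fraction`, sigma `halo_sigma`); a uniform Poisson background
#' of `bg_offset` counts/px is added, then Poisson shot noise, Gaussian
#' read noise, clipping and quantization to `bit_depth`. With
#' `photon_scale = 0`, `bg_offset = 0` and `read_noise_sd = 0` the output
#' is identically 0. Uses the current RNG state.
#'
#' @param coords 0-based subpixel focus coordinates (`row`, `col` matrix).
#' @param params a `synth_params`.
#' @return integer-valued numeric matrix.
#' @export
render_channel <- function(coords, params) {
  shape <- params$image_shape
  pts <- .splat(coords, shape)
  g <- .gauss_kernels(params$psf_sigma)$g0
  lam <- .conv_sep(pts, g, g) * (1 - params$halo_fraction)
  if (params$halo_fraction > 0) {
    gh <- .gauss_kernels(params$halo_sigma)$g0
    lam <- lam + .conv_sep(pts, gh, gh) * params$halo_fraction
  }
  lam <- lam * params$photon_scale + params$bg_offset
  lam[lam < 0] <- 0
  img <- matrix(stats::rpois(length(lam), lam), shape[1L], shape[2L])
  if (params$read_noise_sd > 0)
    img <- img + matrix(stats::rnorm(length(img), 0, params$read_noise_sd),
                        shape[1L], shape[2L])
  maxv <- 2^params$bit_depth - 1
  matrix(pmin(pmax(round(img), 0), maxv), shape[1L], shape[2L])
}

#' Generate one synthetic two-channel sample with ground truth
#'
#' Builds the nucleus ROI, island masks, channel-A (pan-NPC) foci over the
#' pore-rich region only -- islands contain zero channel-A foci by
#' construction -- and channel-B (single-Nup) foci inside islands (uniform
#' or boundary-biased) plus pore-rich channel-B foci at the same density,
#' then renders both channels. Bit-identical across runs for a fixed
#' `params$seed`.
#'
#' @param params a [synth_params()].
#' @param sample_id sample identifier.
#' @param condition list with `inhibitor`, `treatment_hours`, `antibody`.
#' @return list with `sample` (a `raw_sample`) and `truth` (class
#'   `ground_truth`: `nucleus_mask`, `island_masks`, `pore_rich_foci`,
#'   `island_foci` (list per island), `b_pore_rich_foci`, `params`).
#' @export
synth_sample <- function(params = synth_params(), sample_id = "synth_1",
                         condition = list(inhibitor = "none",
                                          treatment_hours = 0,
                                          antibody = "synthetic")) {
  stopifnot(inherits(params, "synth_params"))
  .with_seed(params$seed, {
    geom <- .nucleus_geometry(params)
    nucleus <- geom(params$nucleus_radius)
    # the imaged NE surface extends beyond the analysis ROI: a manually
    # outlined nuclear region sits inside the flat bottom surface, so the
    # pan-NPC texture must run all the way to (and past) the ROI edge
    ne_surface <- geom(params$nucleus_radius + params$ne_margin)
    islands <- sample_island_shapes(params, nucleus)
    island_union <- Reduce(`|`, islands,
                           matrix(FALSE, nrow(nucleus), ncol(nucleus)))
    pore_rich <- ne_surface & !island_union
    a_foci <- place_foci(pore_rich, params$pore_rich_density,
                         params$pixel_size, mode = "uniform",
                         min_dist = params$hard_core_dist)
    island_foci <- lapply(islands, function(m)
      place_foci(m, params$island_foci_density, params$pixel_size,
                 mode = params$placement_mode,
                 bias_strength = params$bias_strength))
    b_bg <- place_foci(pore_rich, params$island_foci_density,
                       params$pixel_size, mode = "uniform")
    ch_a <- render_channel(a_foci, params)
    all_b <- do.call(rbind, c(island_foci, list(b_bg)))
    ch_b <- render_channel(all_b, params)
    truth <- structure(list(nucleus_mask = nucleus, island_masks = islands,
                            pore_rich_foci = a_foci,
                            island_foci = island_foci,
                            b_pore_rich_foci = b_bg, params = params),
                       class = "ground_truth")
    sample <- new_raw_sample(sample_id = sample_id, condition = condition,
                             channel_a = ch_a, channel_b = ch_b,
                             nucleus_mask = nucleus,
                             pixel_size = params$pixel_size,
                             bit_depth = params$bit_depth)
    list(sample = sample, truth = truth)
  })
}
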