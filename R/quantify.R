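# Quantification of recognized islands: area, focus appearance frequency,
# and the distribution of focus distances from the pore-free/pore-rich
# boundary. Distances come from the exact Euclidean distance transform of
# the island mask against its complement, so boundary pixels sit at
# distance 1 and distances increase inward.

#' Per-island size and appearance-frequency record
#'
#' @param island_mask logical matrix of one island.
#' @param n_foci number of foci assigned to this island.
#' @param pixel_size um per pixel.
#' @param sample_id,island_id identifiers carried into the record.
#' @return one-row data.frame: sample_id, island_id, area_px, area_um2,
#'   n_foci, frequency (foci / um^2).
#' @examples
#' m <- matrix(FALSE, 40, 40); m[5:34, 5:34] <- TRUE
#' island_metrics(m, n_foci = 12, pixel_size = 0.1)
#' @export
island_metrics <- function(island_mask, n_foci, pixel_size,
                           sample_id = "s", island_id = 1L) {
  stopifnot(any(island_mask), pixel_size > 0, n_foci >= 0)
  area_px <- sum(island_mask)
  area_um2 <- area_px * pixel_size^2
  data.frame(sample_id = sample_id, island_id = as.integer(island_id),
             area_px = area_px, area_um2 = area_um2,
             n_foci = as.integer(n_foci),
             frequency = n_foci / area_um2,
             stringsAsFactors = FALSE)
}

#' Euclidean distance field of an island
#'
#' Exact Euclidean distance from every island pixel to the nearest
#' non-island pixel. Pixels on the island rim (4-adjacent to the exterior)
#' have distance 1; the field is `NA` outside the island.
#'
#' @param island_mask logical matrix with at least one `TRUE` pixel and at
#'   least one `FALSE` pixel.
#' @return object of class `distance_field`: numeric matrix of distances
#'   (px), `NA` off-island, with attribute `mask`.
#' @export
distance_field <- function(island_mask) {
  stopifnot(is.matrix(island_mask), any(island_mask), any(!island_mask))
  d <- EBImage::distmap(matrix(as.numeric(island_mask), nrow(island_mask),
                               ncol(island_mask)), metric = "euclidean")
  d <- matrix(as.numeric(d), nrow(island_mask), ncol(island_mask))
  d[!island_mask] <- NA_real_
  structure(d, mask = island_mask, class = "distance_field")
}

#' Bin index of a distance for half-open bins (lo, hi] of width `bin`
#' @noRd
.dist_bin <- function(d, bin) as.integer(ceiling(d / bin - 1e-12))

#' Boundary-distance profile of one island
#'
#' Assigns each focus the distance-field value at its centroid's containing
#' pixel and counts foci and island pixels in half-open distance bins
#' `(lo, hi]` of width `distance_bin` px. The raw frequency is the per-bin
#' focus count divided by the per-bin pixel count.
#'
#' @param foci_coords numeric matrix with columns `row`, `col` (0-based
#'   subpixel coordinates), possibly 0 rows.
#' @param field a `distance_field` of the island.
#' @param distance_bin bin width in px (default 1).
#' @param kind `"observed"` or `"simulated"` (metadata).
#' @return object of class `distance_profile`: list with `bin_lo`, `bin_hi`,
#'   `focus_counts`, `pixel_counts`, `raw_frequency`, `distance_bin`,
#'   `kind`, `n_islands` (= 1).
#' @export
distance_profile <- function(foci_coords, field, distance_bin = 1,
                             kind = "observed") {
  stopifnot(inherits(field, "distance_field"), distance_bin > 0)
  mask <- attr(field, "mask")
  d_px <- field[mask]
  n_bins <- max(.dist_bin(d_px, distance_bin))
  pixel_counts <- tabulate(.dist_bin(d_px, distance_bin), nbins = n_bins)
  focus_counts <- integer(n_bins)
  if (!is.null(foci_coords) && nrow(foci_coords) > 0) {
    # pixel centers sit at integer 0-based coordinates, so the containing
    # pixel of a subpixel coordinate is its nearest integer
    pr <- as.integer(round(foci_coords[, 1L])) + 1L
    pc <- as.integer(round(foci_coords[, 2L])) + 1L
    inside <- pr >= 1L & pr <= nrow(field) & pc >= 1L & pc <= ncol(field)
    if (!all(inside) || anyNA(field[cbind(pr, pc)]))
      stop("focus outside the island mask: assignment bug upstream")
    fb <- .dist_bin(field[cbind(pr, pc)], distance_bin)
    focus_counts <- tabulate(fb, nbins = n_bins)
  }
  structure(list(bin_lo = (seq_len(n_bins) - 1) * distance_bin,
                 bin_hi = seq_len(n_bins) * distance_bin,
                 focus_counts = as.numeric(focus_counts),
                 pixel_counts = pixel_counts,
                 raw_frequency = as.numeric(focus_counts) / pixel_counts,
                 distance_bin = distance_bin, kind = kind, n_islands = 1L),
            class = "distance_profile")
}

#' Aggregate per-island profiles into a condition-level profile
#'
#' Averages the per-island raw frequencies bin-wise -- each island
#' contributes only to the bins it possesses (up to its own maximum
#' distance) -- then normalizes the averaged curve to sum 1.0.
#'
#' @param profiles list of `distance_profile`s with a common bin width.
#' @param kind label for the result (defaults to the first profile's kind).
#' @return a `distance_profile` with `normalized_frequency` added and
#'   `n_islands` = number of profiles. If no profile contains any focus the
#'   normalized frequency is `NA` and attribute `flagged` is `TRUE`.
#' @export
aggregate_profiles <- function(profiles, kind = NULL) {
  stopifnot(length(profiles) >= 1L,
            all(vapply(profiles, inherits, logical(1), "distance_profile")))
  bw <- unique(vapply(profiles, `[[`, numeric(1), "distance_bin"))
  if (length(bw) != 1L) stop("profiles have differing bin widths")
  if (is.null(kind)) kind <- profiles[[1L]]$kind
  n_bins <- max(vapply(profiles, function(p) length(p$focus_counts),
                       integer(1)))
  freq_sum <- numeric(n_bins); n_with <- integer(n_bins)
  fc <- numeric(n_bins); pc <- numeric(n_bins)
  for (p in profiles) {
    nb <- length(p$focus_counts)
    freq_sum[1:nb] <- freq_sum[1:nb] + p$raw_frequency
    n_with[1:nb] <- n_with[1:nb] + 1L
    fc[1:nb] <- fc[1:nb] + p$focus_counts
    pc[1:nb] <- pc[1:nb] + p$pixel_counts
  }
  avg <- freq_sum / n_with
  tot <- sum(avg)
  flagged <- !is.finite(tot) || tot <= 0
  structure(list(bin_lo = (seq_len(n_bins) - 1) * bw,
                 bin_hi = seq_len(n_bins) * bw,
                 focus_counts = fc, pixel_counts = pc,
                 raw_frequency = avg,
                 normalized_frequency = if (flagged) rep(NA_real_, n_bins)
                                        else avg / tot,
                 distance_bin = bw, kind = kind,
                 n_islands = length(profiles)),
            class = "distance_profile", flagged = flagged)
}

#' Split profile bins into boundary-proximal and distal sets
#'
#' Proximal bins are those with upper edge at most `proximal_fraction`
#' times the largest distance present (at least the first bin); the rest are
#' distal. With at least two bins both sets are nonempty.
#'
#' @param profile a `distance_profile`.
#' @param proximal_fraction number in (0, 1); default 0.5.
#' @return list with integer bin indices `proximal` and `distal` (the latter
#'   empty, with attribute `flagged`, for a single-bin profile).
#' @export
split_proximal_distal <- function(profile, proximal_fraction = 0.5) {
  stopifnot(inherits(profile, "distance_profile"),
            proximal_fraction > 0, proximal_fraction < 1)
  n_bins <- length(profile$focus_counts)
  cutoff <- proximal_fraction * profile$bin_hi[n_bins]
  n_prox <- max(1L, sum(profile$bin_hi <= cutoff + 1e-12))
  out <- list(proximal = seq_len(n_prox),
              distal = if (n_prox < n_bins) seq(n_prox + 1L, n_bins)
                       else integer(0))
  attr(out, "flagged") <- n_bins < 2L
  out
}
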