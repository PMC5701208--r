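# Complete-spatial-randomness null for focus positions. For each observed
# island, the same number of foci as actually detected is re-placed
# uniformly at random over the island's pixels (Mersenne-Twister), binned
# on the island's distance field exactly as the observed foci, and the
# per-bin counts are averaged over many repetitions.

#' Simulate the CSR null for one island
#'
#' Draws `n_foci` pixels uniformly with replacement from the island pixels
#' per repetition and averages the per-distance-bin counts over `reps`
#' repetitions. Deterministic given `seed` (Mersenne-Twister).
#'
#' @param field a [distance_field()] of the island.
#' @param n_foci observed focus count for this island (>= 0).
#' @param reps repetitions (default 33029).
#' @param seed integer seed.
#' @param distance_bin bin width in px.
#' @return numeric vector of per-bin mean focus counts (same binning as
#'   [distance_profile()] on this island).
#' @export
simulate_island_null <- function(field, n_foci, reps = 33029L, seed = 1L,
                                 distance_bin = 1) {
  stopifnot(inherits(field, "distance_field"), reps >= 1L, n_foci >= 0L)
  mask <- attr(field, "mask")
  pix_bin <- .dist_bin(field[mask], distance_bin)
  n_bins <- max(pix_bin)
  if (n_foci == 0L) return(numeric(n_bins))
  .with_seed(seed, {
    draws <- sample(pix_bin, reps * n_foci, replace = TRUE)
    tabulate(draws, nbins = n_bins) / reps
  })
}

#' Condition-level simulated distance profile
#'
#' Runs [simulate_island_null()] for every island of a condition (each
#' island on its own reproducible substream of `seed`), converts
#' each island's mean counts into a raw frequency by dividing by that
#' island's per-bin pixel counts, then averages across islands and
#' normalizes to sum 1.0 -- mirroring [aggregate_profiles()] on the
#' observed side exactly.
#'
#' @param fields list of `distance_field`s, one per island.
#' @param n_foci integer vector of observed counts, one per island.
#' @param reps,seed,distance_bin as in [simulate_island_null()].
#' @param island_ids stable integer identity per island; each island's
#'   substream seed derives from (`seed`, its id), so reordering islands
#'   within a condition does not change any island's null.
#' @return a `distance_profile` with `kind = "simulated"`, plus attribute
#'   `island_means`: list of per-island mean count vectors.
#' @export
simulated_condition_profile <- function(fields, n_foci, reps = 33029L,
                                        seed = 1L, distance_bin = 1,
                                        island_ids = seq_along(fields)) {
  stopifnot(length(fields) >= 1L, length(n_foci) == length(fields),
            length(island_ids) == length(fields))
  profs <- vector("list", length(fields))
  means <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    m <- simulate_island_null(fields[[i]], n_foci[i], reps = reps,
                              seed = .substream_seed(seed, island_ids[i]),
                              distance_bin = distance_bin)
    means[[i]] <- m
    mask <- attr(fields[[i]], "mask")
    pc <- tabulate(.dist_bin(fields[[i]][mask], distance_bin),
                   nbins = length(m))
    profs[[i]] <- structure(
      list(bin_lo = (seq_along(m) - 1) * distance_bin,
           bin_hi = seq_along(m) * distance_bin,
           focus_counts = m, pixel_counts = pc,
           raw_frequency = m / pc,
           distance_bin = distance_bin, kind = "simulated", n_islands = 1L),
      class = "distance_profile")
  }
  out <- aggregate_profiles(profs, kind = "simulated")
  attr(out, "island_means") <- means
  out
}
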