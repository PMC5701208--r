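# Pore-free island recognition. Pixels of the pan-NPC channel are clustered
# in the 3-D standardized moment-feature space by K-means for k = 2..20; the
# cluster with the lowest mean pan-NPC intensity is taken as the island
# class, and the cluster number is selected automatically from the trace of
# the island class's within-class variation (WCV): the smallest k at which
# the first difference of the total WCV changes sign from minus to plus,
# i.e. the first strict local minimum of the trace.

#' K-means clustering of standardized feature vectors
#'
#' Lloyd's algorithm with k-means++ initialization, keeping the best of
#' `restarts` runs by total within-cluster sum of squares. Deterministic
#' given `seed`. If the data contain fewer than `k` distinct rows the
#' distinct rows become the clusters (degenerate case, warning).
#'
#' @param features numeric matrix, one row per pixel (as from
#'   [standardize_features()]).
#' @param k integer >= 2.
#' @param seed integer seed for initialization.
#' @param restarts number of k-means++ restarts (>= 1).
#' @return integer vector of cluster labels (1-based), one per row.
#' @export
cluster_pixels <- function(features, k, seed = 1L, restarts = 3L) {
  stopifnot(is.matrix(features), k >= 2L)
  n <- nrow(features)
  if (k > n) stop("k = ", k, " exceeds the number of valid pixels (", n, ")")
  uniq <- unique(features)
  if (nrow(uniq) < k) {
    warning("only ", nrow(uniq), " distinct feature vectors for k = ", k,
            "; returning degenerate clustering")
    return(match(asplit(features, 1), asplit(uniq, 1)))
  }
  .with_seed(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      centers <- .kmeanspp_init(features, k)
      fit <- suppressWarnings(
        stats::kmeans(features, centers = centers, iter.max = 60L,
                      algorithm = "Lloyd"))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    as.integer(best$cluster)
  })
}

#' k-means++ seeding: first center uniform, the rest proportional to the
#' squared distance to the nearest chosen center.
#' @noRd
.kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  d2 <- rowSums((x - matrix(centers[1L, ], n, ncol(x), byrow = TRUE))^2)
  for (j in 2L:k) {
    if (all(d2 <= 0)) idx <- sample.int(n, 1L)
    else idx <- sample.int(n, 1L, prob = d2)
    centers[j, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  # nudge exact duplicates (possible when d2 hits 0) so kmeans accepts them
  dup <- duplicated(centers)
  if (any(dup)) centers[dup, ] <- centers[dup, , drop = FALSE] +
      matrix(1e-9 * seq_len(sum(dup)), sum(dup), ncol(x))
  centers
}

#' Identify the island class: lowest mean pan-NPC intensity
#'
#' Pore-free islands exclude mature NPCs, so among the K-means clusters the
#' one whose pixels are darkest in the pan-NPC channel contains the islands.
#' Ties break toward the smaller label id (with a warning).
#'
#' @param labels integer cluster labels for the valid pixels.
#' @param channel_a_values pan-NPC intensities of the same pixels.
#' @return the island class label (integer).
#' @export
select_island_class <- function(labels, channel_a_values) {
  stopifnot(length(labels) == length(channel_a_values))
  ids <- sort(unique(labels))
  means <- vapply(ids, function(l) mean(channel_a_values[labels == l]),
                  numeric(1))
  lo <- min(means)
  hit <- ids[means <= lo + .Machine$double.eps * max(1, abs(lo))]
  if (length(hit) > 1L)
    warning("tie in island-class mean intensity; choosing label ", min(hit))
  as.integer(min(hit))
}

#' Within-class-variation trace of the island class across k
#'
#' For each k, the WCV of each of the three (standardized) features is the
#' population variance of that feature over the island-class pixels. Each
#' feature's WCV sequence is then min-max normalized across k to [0, 1], and
#' the total WCV is the unweighted mean of the three normalized sequences.
#' First differences `diffs[i] = total[i+1] - total[i]` feed [select_k()].
#'
#' @param features standardized feature matrix (pixels x 3).
#' @param labels_per_k list of label vectors, one per k.
#' @param island_class_per_k integer vector of island-class labels per k.
#' @param k_values integer vector of the k each entry corresponds to.
#' @return object of class `k_selection_trace`: list with `k_values`,
#'   `wcv_per_feature` (k x 3), `wcv_normalized`, `wcv_total`, `diffs`.
#' @export
wcv_total <- function(features, labels_per_k, island_class_per_k, k_values) {
  stopifnot(length(labels_per_k) == length(k_values),
            length(island_class_per_k) == length(k_values))
  pvar <- function(x) mean((x - mean(x))^2)
  wcv <- matrix(NA_real_, length(k_values), ncol(features),
                dimnames = list(NULL, colnames(features)))
  for (i in seq_along(k_values)) {
    sel <- labels_per_k[[i]] == island_class_per_k[i]
    if (!any(sel)) next  # island class empty at this k: excluded
    wcv[i, ] <- apply(features[sel, , drop = FALSE], 2L, pvar)
  }
  usable <- !is.na(wcv[, 1L])
  if (sum(usable) < 3L) stop("fewer than 3 usable k values in the WCV trace")
  norm <- wcv
  for (j in seq_len(ncol(wcv))) {
    rng <- range(wcv[usable, j])
    norm[usable, j] <- if (diff(rng) > 0)
      (wcv[usable, j] - rng[1L]) / diff(rng) else 0
  }
  total <- rowMeans(norm)
  kv <- k_values[usable]
  total <- total[usable]
  structure(list(k_values = kv,
                 wcv_per_feature = wcv[usable, , drop = FALSE],
                 wcv_normalized = norm[usable, , drop = FALSE],
                 wcv_total = total,
                 diffs = diff(total)),
            class = "k_selection_trace")
}

#' Select the cluster number from a WCV trace
#'
#' Returns the smallest k at which the first difference of the total WCV
#' changes sign from minus to plus -- the first strict local minimum of the
#' trace. Zero differences continue the previous sign, so a plateau minimum
#' selects the plateau's smallest k. If the trace has no such sign change
#' (e.g. monotone), falls back to the argmin of the total WCV and flags it.
#'
#' @param trace a `k_selection_trace` from [wcv_total()].
#' @return integer `selected_k` with attribute `fallback` (logical).
#' @export
select_k <- function(trace) {
  stopifnot(inherits(trace, "k_selection_trace"))
  d <- trace$diffs
  if (length(d) < 2L) stop("need at least 2 differences to select k")
  last_neg <- NA_integer_
  for (i in seq_along(d)) {
    if (d[i] < 0) last_neg <- i
    else if (d[i] > 0) {
      if (!is.na(last_neg)) {
        sel <- trace$k_values[last_neg + 1L]
        return(structure(as.integer(sel), fallback = FALSE))
      }
      last_neg <- NA_integer_  # rising from the start: no minimum yet
    }
    # d[i] == 0: plateau, keep the previous sign
  }
  sel <- trace$k_values[which.min(trace$wcv_total)]
  structure(as.integer(sel), fallback = TRUE)
}

#' Extract clean island masks from the island-class label map
#'
#' Binarizes the island class and cleans it morphologically before
#' component analysis: an opening with a disc of radius `cleanup_radius`
#' removes the thin lace of interstitial dark pixels that the island class
#' inevitably picks up between pan-NPC puncta (islands are wide smooth
#' blobs and survive the opening unchanged), then a 3x3 closing and hole
#' filling smooth the island outline. 8-connected components smaller than
#' `min_island_area` (um^2, converted with `pixel_size`) or touching the
#' border of the valid region are dropped (rim artifacts: the analysis
#' concerns islands fully surrounded by pore-rich NE).
#'
#' @param label_map integer matrix of cluster labels (-1 outside the valid
#'   region).
#' @param island_class_id label of the island class.
#' @param valid_mask logical matrix of analyzable pixels.
#' @param min_island_area minimum island area, um^2.
#' @param pixel_size pixel size, um/px.
#' @param cleanup_radius radius (px) of the opening disc; 0 disables.
#' @return list with `island_masks` (list of logical matrices),
#'   `boundaries` (list of logical matrices, 4-adjacency boundary pixels)
#'   and `n_pre_filter` (component count before area/rim filtering).
#' @export
extract_islands <- function(label_map, island_class_id, valid_mask,
                            min_island_area = 4, pixel_size = 0.0645,
                            cleanup_radius = 4L) {
  stopifnot(identical(dim(label_map), dim(valid_mask)), pixel_size > 0)
  bin <- label_map == island_class_id & valid_mask
  if (!any(bin))
    return(list(island_masks = list(), boundaries = list(), n_pre_filter = 0L))
  if (cleanup_radius > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(cleanup_radius) + 1L, "disc")
    bin <- EBImage::opening(bin * 1, brush) > 0.5
  }
  closed <- EBImage::closing(bin * 1, EBImage::makeBrush(3L, "box")) > 0.5
  filled <- EBImage::fillHull(closed * 1) > 0.5
  filled <- filled & valid_mask   # closing may bleed outside the valid region
  lab <- .label8(filled)
  n_comp <- max(lab)
  if (n_comp == 0L)
    return(list(island_masks = list(), boundaries = list(), n_pre_filter = 0L))
  rim <- .boundary4(valid_mask)
  min_px <- min_island_area / pixel_size^2
  masks <- list(); bounds <- list()
  for (i in seq_len(n_comp)) {
    comp <- lab == i
    if (sum(comp) < min_px) next
    if (any(comp & rim)) next
    masks[[length(masks) + 1L]] <- comp
    bounds[[length(bounds) + 1L]] <- .boundary4(comp)
  }
  list(island_masks = masks, boundaries = bounds, n_pre_filter = n_comp)
}

#' Full island segmentation of one sample
#'
#' Runs the complete recognition stage on the pan-NPC channel: moment
#' features, standardization, K-means for every k in `cfg$k_range`,
#' island-class identification, WCV trace, automatic k selection, and island
#' mask extraction.
#'
#' @param sample a `raw_sample` (see [load_sample()] / [synth_sample()]).
#' @param cfg a `run_config` from [run_config()].
#' @return object of class `segmentation_result`: list with `label_map`
#'   (integer matrix, -1 outside the valid region), `island_class_id`,
#'   `island_masks`, `boundaries`, `trace` (`k_selection_trace` with
#'   `selected_k` and `fallback` appended), `valid_mask`, `n_pre_filter`.
#' @export
segment_islands <- function(sample, cfg = run_config()) {
  stack <- local_moment_features(sample$channel_a, window = cfg$feature_window,
                                 roi = sample$nucleus_mask)
  feats <- standardize_features(stack)
  valid <- attr(feats, "valid_mask")
  ca_valid <- sample$channel_a[valid]
  ks <- seq(cfg$k_range[1L], cfg$k_range[2L])
  labels_per_k <- vector("list", length(ks))
  island_per_k <- integer(length(ks))
  for (i in seq_along(ks)) {
    labels_per_k[[i]] <- cluster_pixels(feats, ks[i],
                                        seed = cfg$kmeans_seed + ks[i],
                                        restarts = cfg$kmeans_restarts)
    island_per_k[i] <- select_island_class(labels_per_k[[i]], ca_valid)
  }
  trace <- wcv_total(feats, labels_per_k, island_per_k, ks)
  sel <- select_k(trace)
  trace$selected_k <- as.integer(sel)
  trace$fallback <- attr(sel, "fallback")
  i_sel <- match(trace$selected_k, ks)
  label_map <- matrix(-1L, nrow(sample$channel_a), ncol(sample$channel_a))
  label_map[valid] <- labels_per_k[[i_sel]]
  isl <- extract_islands(label_map, island_per_k[i_sel], valid,
                         min_island_area = cfg$min_island_area,
                         pixel_size = sample$pixel_size,
                         cleanup_radius = cfg$cleanup_radius)
  structure(list(label_map = label_map,
                 island_class_id = island_per_k[i_sel],
                 island_masks = isl$island_masks,
                 boundaries = isl$boundaries,
                 trace = trace,
                 valid_mask = valid,
                 n_pre_filter = isl$n_pre_filter),
            class = "segmentation_result")
}
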