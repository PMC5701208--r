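# Batch orchestration: samplesheet in, tables + review images out. Every
# input sample yields exactly one QC row; individual sample failures are
# logged and flagged but never abort the run. All randomness flows from
# cfg$kmeans_seed and cfg$sim_seed, so a run is deterministic given
# (inputs, config).

#' Run the full pipeline over a samplesheet
#'
#' For each sample: load, segment islands, QC, detect foci, quantify
#' island size/frequency and boundary-distance profiles, and simulate the
#' per-island CSR null. Per condition: aggregated observed and simulated
#' profiles and Brunner-Munzel comparisons (island size and appearance
#' frequency across condition pairs; observed-vs-simulated regional shares
#' within each condition).
#'
#' @param samplesheet data.frame or CSV path with columns `sample_id`,
#'   `channel_a_path`, `channel_b_path`, `mask_path`, `inhibitor`,
#'   `treatment_hours`, `antibody`, `pixel_size_um`.
#' @param cfg a [run_config()].
#' @param out_dir output directory (created); receives `islands.csv`,
#'   `profiles.csv`, `stats.csv`, `qc.csv`, `run.log`, and per-sample
#'   `<id>_labels.tif` / `<id>_overlay.png`.
#' @param samples optional named list of preloaded `raw_sample`s keyed by
#'   `sample_id`, bypassing file loading (the samplesheet still defines
#'   order and conditions).
#' @return (invisibly) list with the four tables.
#' @export
run_pipeline <- function(samplesheet, cfg = run_config(), out_dir,
                         samples = NULL) {
  if (is.character(samplesheet)) samplesheet <- utils::read.csv(
    samplesheet, stringsAsFactors = FALSE)
  stopifnot(is.data.frame(samplesheet))
  if (nrow(samplesheet) == 0L) stop("empty samplesheet")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("porefree run: %d sample(s)", nrow(samplesheet)),
                 sprintf("kmeans_seed=%d sim_seed=%d sim_reps=%d",
                         cfg$kmeans_seed, cfg$sim_seed, cfg$sim_reps))
  logf <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  qc_rows <- list(); island_rows <- list()
  per_island <- list()  # per accepted island: profile, sim means, meta

  for (si in seq_len(nrow(samplesheet))) {
    row <- samplesheet[si, ]
    cond <- paste(row$inhibitor, row$treatment_hours, row$antibody,
                  sep = "_")
    sample <- tryCatch({
      if (!is.null(samples) && row$sample_id %in% names(samples))
        samples[[row$sample_id]]
      else load_sample(row$channel_a_path, row$channel_b_path,
                       row$mask_path,
                       condition = list(inhibitor = row$inhibitor,
                                        treatment_hours = row$treatment_hours,
                                        antibody = row$antibody),
                       pixel_size = row$pixel_size_um,
                       sample_id = row$sample_id)
    }, error = function(e) {
      logf("sample %s: load failed: %s", row$sample_id, conditionMessage(e))
      NULL
    })
    if (is.null(sample)) {
      qc_rows[[si]] <- data.frame(sample_id = row$sample_id,
                                  saturation_fraction = NA_real_,
                                  blur_metric = NA_real_,
                                  n_islands_pre_filter = 0L,
                                  n_islands_post_filter = 0L,
                                  flags = "LOAD_ERROR", accepted = FALSE,
                                  stringsAsFactors = FALSE)
      next
    }
    seg <- tryCatch(segment_islands(sample, cfg), error = function(e) {
      logf("sample %s: segmentation failed: %s", row$sample_id,
           conditionMessage(e))
      NULL
    })
    qc <- compute_qc(sample, seg, cfg)
    if (!is.null(seg) && isTRUE(seg$trace$fallback))
      logf("sample %s: k-selection FALLBACK (no WCV sign change), k=%d",
           row$sample_id, seg$trace$selected_k)
    qc_rows[[si]] <- as.data.frame(qc)
    if (!qc$accepted) {
      logf("sample %s rejected: %s", row$sample_id, qc$flags)
      next
    }

    fs <- detect_foci(sample$channel_b, seg$island_masks, cfg = cfg,
                      mode = "islands")
    .write_label_tiff(seg$island_masks, dim(sample$channel_a),
                      file.path(out_dir,
                                paste0(row$sample_id, "_labels.tif")))
    .write_overlay_png(sample$channel_a, seg$boundaries, fs$foci,
                       file.path(out_dir,
                                 paste0(row$sample_id, "_overlay.png")))

    for (ii in seq_along(seg$island_masks)) {
      n_foci <- sum(fs$foci$island_id == ii, na.rm = TRUE)
      rec <- island_metrics(seg$island_masks[[ii]], n_foci,
                            sample$pixel_size,
                            sample_id = row$sample_id, island_id = ii)
      rec$condition <- cond
      island_rows[[length(island_rows) + 1L]] <- rec

      field <- distance_field(seg$island_masks[[ii]])
      fc <- fs$foci[which(fs$foci$island_id == ii), c("row", "col"),
                    drop = FALSE]
      prof <- distance_profile(as.matrix(fc), field,
                               distance_bin = cfg$distance_bin)
      sim_means <- simulate_island_null(
        field, n_foci, reps = cfg$sim_reps,
        seed = .substream_seed(cfg$sim_seed, si * 1000L + ii),
        distance_bin = cfg$distance_bin)
      per_island[[length(per_island) + 1L]] <-
        list(condition = cond, profile = prof, sim_means = sim_means,
             field = field)
    }
  }

  qc_tab <- do.call(rbind, qc_rows)
  islands_tab <- if (length(island_rows)) do.call(rbind, island_rows)
                 else data.frame()

  profile_rows <- list(); stats_rows <- list()
  conds <- unique(vapply(per_island, `[[`, character(1), "condition"))
  for (cd in conds) {
    members <- per_island[vapply(per_island, function(x)
      x$condition == cd, logical(1))]
    obs <- lapply(members, `[[`, "profile")
    agg_obs <- aggregate_profiles(obs, kind = "observed")
    sim_profs <- lapply(members, function(m) {
      structure(list(bin_lo = (seq_along(m$sim_means) - 1) * cfg$distance_bin,
                     bin_hi = seq_along(m$sim_means) * cfg$distance_bin,
                     focus_counts = m$sim_means,
                     pixel_counts = m$profile$pixel_counts,
                     raw_frequency = m$sim_means / m$profile$pixel_counts,
                     distance_bin = cfg$distance_bin, kind = "simulated",
                     n_islands = 1L), class = "distance_profile")
    })
    agg_sim <- aggregate_profiles(sim_profs, kind = "simulated")
    for (agg in list(agg_obs, agg_sim)) {
      profile_rows[[length(profile_rows) + 1L]] <- data.frame(
        condition = cd, kind = agg$kind, bin_lo_px = agg$bin_lo,
        bin_hi_px = agg$bin_hi, focus_count = agg$focus_counts,
        pixel_count = agg$pixel_counts, raw_frequency = agg$raw_frequency,
        normalized_frequency = agg$normalized_frequency,
        n_islands = agg$n_islands, stringsAsFactors = FALSE)
    }
    cmp <- suppressMessages(
      compare_profiles(obs, lapply(members, `[[`, "sim_means"),
                       proximal_fraction = cfg$proximal_fraction))
    if (nrow(cmp)) {
      cmp <- cbind(comparison_id = paste0("profile_", cd, "_", cmp$region),
                   measure = "regional_share", condition = cd, cmp,
                   stringsAsFactors = FALSE)
      stats_rows[[length(stats_rows) + 1L]] <- cmp
    }
  }

  if (nrow(islands_tab) && length(unique(islands_tab$condition)) >= 2L) {
    for (ms in c("area_um2", "frequency")) {
      tab <- suppressMessages(compare_conditions(islands_tab, ms))
      if (nrow(tab)) {
        tab <- cbind(comparison_id = paste0(ms, "_", tab$group_x, "_vs_",
                                            tab$group_y), tab,
                     stringsAsFactors = FALSE)
        stats_rows[[length(stats_rows) + 1L]] <- tab
      }
    }
  }

  profiles_tab <- if (length(profile_rows)) do.call(rbind, profile_rows)
                  else data.frame()
  stats_tab <- if (length(stats_rows)) {
    all_cols <- unique(unlist(lapply(stats_rows, names)))
    do.call(rbind, lapply(stats_rows, function(d) {
      d[setdiff(all_cols, names(d))] <- NA
      d[all_cols]
    }))
  } else data.frame()

  utils::write.csv(qc_tab, file.path(out_dir, "qc.csv"), row.names = FALSE)
  utils::write.csv(islands_tab, file.path(out_dir, "islands.csv"),
                   row.names = FALSE)
  utils::write.csv(profiles_tab, file.path(out_dir, "profiles.csv"),
                   row.names = FALSE)
  utils::write.csv(stats_tab, file.path(out_dir, "stats.csv"),
                   row.names = FALSE)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(list(qc = qc_tab, islands = islands_tab,
                 profiles = profiles_tab, stats = stats_tab))
}

#' Write a synthetic sample to disk
#'
#' Emits the two channel TIFFs, the nucleus-mask TIFF, a ground-truth
#' manifest CSV (focus coordinates with island ids; island id 0 denotes
#' pore-rich channel-B foci, -1 the channel-A pan-NPC foci) and the
#' generator parameters as a flat TOML file.
#'
#' @param ss result of [synth_sample()].
#' @param dir output directory.
#' @return (invisibly) one samplesheet row (data.frame) referencing the
#'   written files.
#' @export
write_synth_sample <- function(ss, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- ss$truth$params
  id <- ss$sample$sample_id
  maxv <- 2^p$bit_depth - 1
  paths <- file.path(dir, paste0(id, c("_chA.tif", "_chB.tif", "_mask.tif")))
  tiff::writeTIFF(ss$sample$channel_a / maxv, paths[1L],
                  bits.per.sample = p$bit_depth)
  tiff::writeTIFF(ss$sample$channel_b / maxv, paths[2L],
                  bits.per.sample = p$bit_depth)
  tiff::writeTIFF((ss$sample$nucleus_mask * 1), paths[3L],
                  bits.per.sample = 8L)
  manifest <- rbind(
    if (nrow(ss$truth$pore_rich_foci))
      data.frame(channel = "A", island_id = -1L, ss$truth$pore_rich_foci),
    do.call(rbind, lapply(seq_along(ss$truth$island_foci), function(i)
      if (nrow(ss$truth$island_foci[[i]]))
        data.frame(channel = "B", island_id = i, ss$truth$island_foci[[i]]))),
    if (nrow(ss$truth$b_pore_rich_foci))
      data.frame(channel = "B", island_id = 0L, ss$truth$b_pore_rich_foci))
  utils::write.csv(manifest, file.path(dir, paste0(id, "_truth.csv")),
                   row.names = FALSE)
  keep <- vapply(p, function(x) is.numeric(x) || is.character(x) ||
                   is.logical(x), logical(1))
  toml <- vapply(names(p)[keep], function(k) {
    v <- p[[k]]
    val <- if (is.character(v)) sprintf('"%s"', v)
           else if (length(v) > 1L) sprintf("[%s]",
                                            paste(format(v), collapse = ", "))
           else format(v)
    sprintf("%s = %s", k, val)
  }, character(1))
  writeLines(toml, file.path(dir, paste0(id, "_params.toml")))
  invisible(data.frame(sample_id = id, channel_a_path = paths[1L],
                       channel_b_path = paths[2L], mask_path = paths[3L],
                       inhibitor = ss$sample$condition$inhibitor,
                       treatment_hours = ss$sample$condition$treatment_hours,
                       antibody = ss$sample$condition$antibody,
                       pixel_size_um = p$pixel_size,
                       stringsAsFactors = FALSE))
}
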