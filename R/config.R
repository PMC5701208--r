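# Run configuration. All tunables of the pipeline live in one object; every
# source of randomness flows from its two named seeds (kmeans_seed,
# sim_seed). A flat TOML file with the same field names can be read with
# read_run_config().

#' Pipeline run configuration
#'
#' @param k_range inclusive c(lo, hi) of cluster numbers tried (lo >= 2).
#' @param kmeans_seed seed for K-means initialization.
#' @param kmeans_restarts k-means++ restarts per k.
#' @param feature_window odd window side for the moment features, px.
#' @param curvature_sigma Gaussian-derivative scale for mean curvature, px.
#' @param min_island_area minimum island area kept, um^2.
#' @param cleanup_radius disc radius (px) of the label-map opening that
#'   strips interstitial speckle before island component analysis.
#' @param min_focus_area,max_focus_area focus component area band, px.
#' @param saturation_fraction_limit QC: max tolerated fraction of in-mask
#'   pixels at the dtype maximum.
#' @param blur_metric_limit QC: minimum normalized gradient energy at the
#'   nucleus edge (lower = blurrier).
#' @param sim_reps CSR-null repetitions per island.
#' @param sim_seed seed for the null simulation.
#' @param distance_bin distance-profile bin width, px.
#' @param proximal_fraction proximal/distal split parameter in (0, 1).
#' @param alpha significance level for the label ladder.
#' @return list of class `run_config`.
#' @export
run_config <- function(k_range = c(2L, 20L), kmeans_seed = 1L,
                       kmeans_restarts = 2L, feature_window = 3L,
                       curvature_sigma = 1.0, min_island_area = 4,
                       cleanup_radius = 4L,
                       min_focus_area = 2L, max_focus_area = 100L,
                       saturation_fraction_limit = 0.001,
                       blur_metric_limit = 0.02,
                       sim_reps = 33029L, sim_seed = 1L, distance_bin = 1,
                       proximal_fraction = 0.5, alpha = 0.05) {
  stopifnot(length(k_range) == 2L, k_range[1L] >= 2L,
            k_range[2L] >= k_range[1L],
            sim_reps >= 1L, proximal_fraction > 0, proximal_fraction < 1,
            feature_window %% 2L == 1L, min_focus_area >= 1L,
            max_focus_area >= min_focus_area)
  structure(as.list(environment()), class = "run_config")
}

#' Read a run configuration from a flat TOML file
#'
#' Reads the flat `key = value` dialect the tool writes and consumes
#' (scalars and two-element arrays only; `#` comments allowed). Unknown
#' keys are an error; missing keys take [run_config()] defaults.
#'
#' @param path TOML file path.
#' @param ... overrides applied after the file (e.g. from CLI flags).
#' @return a `run_config`.
#' @export
read_run_config <- function(path, ...) {
  vals <- .parse_flat_toml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  vals[names(list(...))] <- list(...)
  do.call(run_config, vals)
}

#' @noRd
.parse_flat_toml <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^\\[", lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.+)$", ln))[[1L]]
    if (length(m) != 3L) stop("cannot parse config line: ", ln)
    key <- m[2L]; raw <- trimws(m[3L])
    out[[key]] <- .parse_toml_value(raw)
  }
  out
}

#' @noRd
.parse_toml_value <- function(raw) {
  if (grepl("^\\[.*\\]$", raw)) {
    parts <- trimws(strsplit(sub("^\\[(.*)\\]$", "\\1", raw), ",")[[1L]])
    return(vapply(parts, function(p) .parse_toml_value(p), numeric(1),
                  USE.NAMES = FALSE))
  }
  if (grepl('^".*"$', raw)) return(sub('^"(.*)"$', "\\1", raw))
  if (raw %in% c("true", "false")) return(raw == "true")
  v <- suppressWarnings(as.numeric(raw))
  if (is.na(v)) stop("cannot parse config value: ", raw)
  v
}
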