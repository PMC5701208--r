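# Nonparametric condition comparisons. The Brunner-Munzel test is used
# throughout: it tests the stochastic-superiority probability
# p = P(X < Y) + 0.5 P(X = Y) against 0.5 and, unlike Wilcoxon, stays valid
# under unequal variances/shapes, which island-size and frequency
# distributions show strongly.

#' Brunner-Munzel two-sample rank test
#'
#' Computes the stochastic-superiority estimate
#' \eqn{\hat p = P(X<Y) + 0.5 P(X=Y)} from pooled midranks, the studentized
#' statistic with rank-based variance estimates, Satterthwaite degrees of
#' freedom, and a two-sided p-value from the t distribution.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @return object of class `bm_test` (a list): `statistic`, `df`, `p_value`,
#'   `p_hat`, `n_x`, `n_y`, `significance_label` (`***`, `**`, `*`, `N.S.`
#'   at 0.001/0.01/0.05).
#' @examples
#' brunner_munzel(c(1, 2, 3, 4), c(2, 3, 4, 5))$p_hat  # 0.71875
#' @export
brunner_munzel <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop("both samples need at least 2 values")
  r <- rank(c(x, y))
  r1 <- rank(x); r2 <- rank(y)
  rx <- r[seq_len(n1)]; ry <- r[n1 + seq_len(n2)]
  m1 <- mean(rx); m2 <- mean(ry)
  p_hat <- (m2 - (n2 + 1) / 2) / n1
  v1 <- sum((rx - r1 - m1 + (n1 + 1) / 2)^2) / (n1 - 1)
  v2 <- sum((ry - r2 - m2 + (n2 + 1) / 2)^2) / (n2 - 1)
  pooled <- n1 * v1 + n2 * v2
  if (pooled <= 0) {
    # zero rank variance arises two ways: everything tied (no information)
    # or complete separation of the two samples (overwhelming evidence)
    if (p_hat > 0 && p_hat < 1)
      stop("DEGENERATE_SAMPLES: zero pooled rank variance (all values tied)")
    return(structure(list(statistic = sign(p_hat - 0.5) * Inf, df = NA_real_,
                          p_value = 0, p_hat = p_hat, n_x = n1, n_y = n2,
                          significance_label = "***"),
                     class = "bm_test"))
  }
  statistic <- n1 * n2 * (m2 - m1) / (n1 + n2) / sqrt(pooled)
  df <- pooled^2 / ((n1 * v1)^2 / (n1 - 1) + (n2 * v2)^2 / (n2 - 1))
  p_value <- 2 * stats::pt(abs(statistic), df, lower.tail = FALSE)
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 p_hat = p_hat, n_x = n1, n_y = n2,
                 significance_label = .sig_label(p_value)),
            class = "bm_test")
}

#' @noRd
.sig_label <- function(p) {
  if (!is.finite(p)) return(NA_character_)
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*"
  else "N.S."
}

#' Compare island measures across conditions
#'
#' One Brunner-Munzel test per condition pair on a per-island measure
#' (island area in um^2 or focus appearance frequency), each island
#' contributing one value. By default all unordered pairs of conditions are
#' compared; pass `pairs` to restrict (e.g. inhibitor contrasts at matched
#' time and antibody). Conditions with fewer than 2 islands are skipped
#' with a message.
#'
#' @param records data.frame of island records with a `condition` column
#'   (as from [island_metrics()] rows plus a condition label).
#' @param measure `"area_um2"` or `"frequency"`.
#' @param pairs optional 2-column character matrix of condition pairs.
#' @return data.frame: one row per tested pair with group medians and
#'   quartiles (boxplot conventions: 25/75% box, 5/95% whiskers), the test
#'   statistic, df, p-value and significance label.
#' @export
compare_conditions <- function(records, measure = c("area_um2", "frequency"),
                               pairs = NULL) {
  measure <- match.arg(measure)
  stopifnot(is.data.frame(records), "condition" %in% names(records),
            measure %in% names(records))
  conds <- unique(records$condition)
  if (is.null(pairs)) {
    if (length(conds) < 2L) stop("need at least 2 conditions")
    pairs <- t(utils::combn(conds, 2L))
  }
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    gx <- records[records$condition == pairs[i, 1L], measure]
    gy <- records[records$condition == pairs[i, 2L], measure]
    if (length(gx) < 2L || length(gy) < 2L) {
      message("skipping pair ", pairs[i, 1L], " vs ", pairs[i, 2L],
              ": fewer than 2 islands in a group")
      next
    }
    bm <- tryCatch(brunner_munzel(gx, gy), error = function(e) NULL)
    if (is.null(bm)) {
      message("skipping pair ", pairs[i, 1L], " vs ", pairs[i, 2L],
              ": degenerate samples")
      next
    }
    qx <- stats::quantile(gx, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE)
    qy <- stats::quantile(gy, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      measure = measure,
      group_x = pairs[i, 1L], group_y = pairs[i, 2L],
      n_x = bm$n_x, n_y = bm$n_y,
      median_x = qx[3L], median_y = qy[3L],
      q25_x = qx[2L], q75_x = qx[4L], q25_y = qy[2L], q75_y = qy[4L],
      w05_x = qx[1L], w95_x = qx[5L], w05_y = qy[1L], w95_y = qy[5L],
      p_hat = bm$p_hat, statistic = bm$statistic, df = bm$df,
      p_value = bm$p_value, label = bm$significance_label,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(data.frame())
  do.call(rbind, rows)
}

#' Observed-vs-simulated comparison of regional focus shares
#'
#' For each region (boundary-proximal, distal), reduces every island to the
#' share of its foci falling in that region -- observed shares from the
#' observed counts, simulated shares from the CSR per-bin mean counts --
#' and compares the two per-island samples with [brunner_munzel()]. The
#' proximal/distal split is taken per island on its own bins. Islands with
#' zero observed foci are excluded (message).
#'
#' @param obs_profiles list of per-island observed `distance_profile`s.
#' @param sim_means list of per-island simulated mean-count vectors (as the
#'   `island_means` attribute of [simulated_condition_profile()]).
#' @param proximal_fraction split parameter, see [split_proximal_distal()].
#' @return data.frame with one row per region: n islands, mean shares, and
#'   the Brunner-Munzel results.
#' @export
compare_profiles <- function(obs_profiles, sim_means,
                             proximal_fraction = 0.5) {
  stopifnot(length(obs_profiles) == length(sim_means))
  sh_obs <- list(proximal = numeric(0), distal = numeric(0))
  sh_sim <- list(proximal = numeric(0), distal = numeric(0))
  n_excluded <- 0L
  for (i in seq_along(obs_profiles)) {
    p <- obs_profiles[[i]]
    tot_obs <- sum(p$focus_counts)
    tot_sim <- sum(sim_means[[i]])
    if (tot_obs <= 0 || tot_sim <= 0) { n_excluded <- n_excluded + 1L; next }
    sp <- split_proximal_distal(p, proximal_fraction)
    for (reg in c("proximal", "distal")) {
      idx <- sp[[reg]]
      sh_obs[[reg]] <- c(sh_obs[[reg]], sum(p$focus_counts[idx]) / tot_obs)
      sh_sim[[reg]] <- c(sh_sim[[reg]], sum(sim_means[[i]][idx]) / tot_sim)
    }
  }
  if (n_excluded > 0L)
    message(n_excluded, " island(s) with zero foci excluded from the ",
            "profile comparison")
  rows <- list()
  for (reg in c("proximal", "distal")) {
    o <- sh_obs[[reg]]; s <- sh_sim[[reg]]
    bm <- tryCatch(brunner_munzel(s, o), error = function(e) NULL)
    rows[[reg]] <- data.frame(
      region = reg, n_islands = length(o),
      mean_share_observed = if (length(o)) mean(o) else NA_real_,
      mean_share_simulated = if (length(s)) mean(s) else NA_real_,
      p_hat = if (is.null(bm)) NA_real_ else bm$p_hat,
      statistic = if (is.null(bm)) NA_real_ else bm$statistic,
      df = if (is.null(bm)) NA_real_ else bm$df,
      p_value = if (is.null(bm)) NA_real_ else bm$p_value,
      label = if (is.null(bm)) NA_character_ else bm$significance_label,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
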