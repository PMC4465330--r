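## Epoching and trajectory construction.
##
## The monitor samples every 2 s; analysis operates on 1-minute epochs
## (arithmetic mean of contained samples). Epochs covered by fewer than 50%
## of the nominal 30 samples are kept but marked missing (mean_value = NA)
## rather than interpolated.

EPOCH_MIN_SAMPLES <- 15L   # 50% of the nominal 30 samples per minute

## epoch index of a time stamp. Emitted times are quantized to 1e-7 h, so a
## boundary sample can sit up to 5e-8 h (3e-6 min) below its true epoch
## start; the 1e-4-minute slack absorbs that while staying far below the
## 1/30-minute sample spacing.
epoch_index <- function(t_h) as.integer(floor(t_h * 60 + 1e-4))

#' Average 2-second vitals streams into 1-minute epochs
#'
#' Epochs are half-open `[start, start + 1 min)` bins aligned to the birth
#' clock. Each epoch records the arithmetic mean of its samples and the
#' sample count; epochs with fewer than `min_samples` samples are marked
#' missing (`mean_value = NA`). Epochs never containing a sample do not
#' appear.
#'
#' @param vitals data.frame of vitals samples (`piglet_id`, `channel`,
#'   `t_h`, `value`), sorted in time within each (piglet, channel).
#' @param min_samples coverage threshold (default 15 of the nominal 30).
#' @return data.table(piglet_id, channel, epoch_start_h, mean_value,
#'   n_samples) sorted by piglet, channel, epoch.
#' @export
downsample_to_epochs <- function(vitals, min_samples = EPOCH_MIN_SAMPLES) {
  v <- as.data.table(vitals)
  unsorted <- v[, .(bad = any(diff(t_h) <= 0)), by = .(piglet_id, channel)]
  if (nrow(unsorted) && any(unsorted$bad)) {
    nec_abort("vitals stream not strictly increasing in t_h within (piglet_id, channel)",
              "nec_ordering_error")
  }
  epochs <- v[, .(mean_value = mean(value), n_samples = .N),
              by = .(piglet_id, channel, epoch = epoch_index(t_h))]
  epochs[n_samples < min_samples, mean_value := NA_real_]
  epochs[, epoch_start_h := epoch / 60]
  setorder(epochs, piglet_id, channel, epoch)
  epochs[, .(piglet_id, channel, epoch_start_h, mean_value, n_samples)]
}

#' Per-animal baseline from the first hour of recording
#'
#' The baseline of each (piglet, channel) is the mean of non-missing epoch
#' means in `[first epoch, first epoch + window_h)`. Animals whose window
#' contains no usable epoch are excluded from the result (with a message).
#'
#' @param epochs output of [downsample_to_epochs()].
#' @param window_h baseline window length in hours (default 1).
#' @return data.table(piglet_id, channel, baseline, n_epochs).
#' @export
compute_baseline <- function(epochs, window_h = 1.0) {
  e <- as.data.table(epochs)
  base <- e[, {
    start <- min(epoch_start_h)
    win <- epoch_start_h < start + window_h - 1e-9
    ok <- win & !is.na(mean_value)
    .(baseline = if (any(ok)) mean(mean_value[ok]) else NA_real_,
      n_epochs = sum(ok))
  }, by = .(piglet_id, channel)]
  dropped <- base[is.na(baseline)]
  if (nrow(dropped)) {
    message("compute_baseline: no usable epochs in the baseline window for ",
            nrow(dropped), " (piglet, channel) pair(s); excluded")
    base <- base[!is.na(baseline)]
  }
  base[]
}

#' Censoring-aware group trajectories on a coarse grid
#'
#' At each grid time `t` (0, 3, ..., 96 h by default), every piglet with
#' `death_h > t` (strictly: a death on a grid point excludes that point)
#' contributes the mean of its non-missing epochs in the centered window
#' `[t - step/2, t + step/2)`; dead animals are never carried forward. Group
#' mean, SEM (absent when fewer than two animals contribute) and the number
#' of contributing animals are reported per channel, group and grid time.
#'
#' @param epochs output of [downsample_to_epochs()].
#' @param piglets the cohort's piglet table (`piglet_id`, `group`, `death_h`).
#' @param grid_step_h grid spacing in hours (default 3).
#' @param study_end_h end of the grid (default 96).
#' @return data.table(channel, grid_h, group, mean, sem, n_alive); grid cells
#'   where no animal of a group contributes are omitted.
#' @export
group_trajectory <- function(epochs, piglets, grid_step_h = 3,
                             study_end_h = 96) {
  e <- as.data.table(epochs)[!is.na(mean_value)]
  p <- as.data.table(piglets)[, .(piglet_id, group, death_h)]
  grid <- seq(0, study_end_h, by = grid_step_h)
  half <- grid_step_h / 2
  out <- vector("list", length(grid))
  e <- p[e, on = "piglet_id"]
  for (k in seq_along(grid)) {
    t <- grid[k]
    win <- e[epoch_start_h >= t - half & epoch_start_h < t + half &
               (is.na(death_h) | death_h > t)]
    if (!nrow(win)) next
    per_animal <- win[, .(v = mean(mean_value)), by = .(channel, group, piglet_id)]
    out[[k]] <- per_animal[, .(
      grid_h = t, mean = mean(v),
      sem = if (.N >= 2L) sd(v) / sqrt(.N) else NA_real_,
      n_alive = .N
    ), by = .(channel, group)]
  }
  traj <- rbindlist(out)
  setorder(traj, channel, group, grid_h)
  traj[]
}
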