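## Peri-prandial StO2 variability: the feeding-response statistic.
##
## For each of the first two enteral feeds, the StO2 epochs in the 15-minute
## windows just before and just after the feed are averaged and the unsigned
## percent change of the post-window mean relative to the pre-window mean is
## taken. A piglet's statistic is the mean over its usable feeds; groups are
## summarized three ways and as pooled NEC vs No-NEC.

WINDOW_MIN <- 15L          # window length in epochs (minutes)
WINDOW_MIN_EPOCHS <- 8L    # minimum non-missing epochs per window

#' Peri-prandial window statistic for a single feed
#'
#' Pre window: epochs starting in `[t_feed - 15 min, t_feed)`; post window:
#' epochs starting in `[t_feed, t_feed + 15 min)` (i.e. covering the
#' interval just after the feed). Windows with fewer than `min_epochs`
#' non-missing epochs cause the feed to be skipped.
#'
#' @param epochs StO2 epochs of one piglet ([downsample_to_epochs()] rows
#'   with `channel == "STO2"`).
#' @param feed_t_h feed time (hours).
#' @param signed if `FALSE` (default) the unsigned percent change is
#'   returned; if `TRUE` the signed change (post - pre)/pre * 100.
#' @param min_epochs coverage threshold per window.
#' @return one-row data.table(pre_mean, post_mean, pct_change), or `NULL`
#'   (with a message) when coverage is insufficient.
#' @export
feed_window_stat <- function(epochs, feed_t_h, signed = FALSE,
                             min_epochs = WINDOW_MIN_EPOCHS) {
  e <- as.data.table(epochs)
  w <- WINDOW_MIN / 60
  pre <- e[epoch_start_h >= feed_t_h - w - 1e-9 & epoch_start_h < feed_t_h - 1e-9 &
             !is.na(mean_value), mean_value]
  post <- e[epoch_start_h >= feed_t_h - 1e-9 & epoch_start_h < feed_t_h + w - 1e-9 &
              !is.na(mean_value), mean_value]
  if (length(pre) < min_epochs || length(post) < min_epochs) {
    message(sprintf("feed_window_stat: insufficient coverage around feed at %g h (pre %d, post %d epochs); skipped",
                    feed_t_h, length(pre), length(post)))
    return(NULL)
  }
  pre_mean <- mean(pre)
  post_mean <- mean(post)
  change <- (post_mean - pre_mean) / pre_mean * 100
  data.table(pre_mean = pre_mean, post_mean = post_mean,
             pct_change = if (signed) change else abs(change))
}

#' Cohort-level peri-prandial variability over the first feeds
#'
#' Computes [feed_window_stat()] for each piglet's first `n_feeds` enteral
#' feeds, averages the percent changes per piglet, and summarizes by group
#' (three severity groups plus pooled NEC = fulminant + non-fulminant vs
#' No-NEC). Piglets with no usable feed window contribute nothing.
#'
#' @param epochs cohort epochs ([downsample_to_epochs()]); only the STO2
#'   channel is used.
#' @param feeds the cohort's feed table.
#' @param piglets the cohort's piglet table.
#' @param n_feeds number of leading feeds entering the statistic (default 2).
#' @param signed passed to [feed_window_stat()].
#' @return list with `per_feed` (piglet, feed_index, window means, pct
#'   change), `per_piglet` (piglet statistic and group), and `summary`
#'   (rows F_NEC/NF_NEC/NO_NEC/NEC with mean, sd, n).
#' @export
cohort_variability <- function(epochs, feeds, piglets, n_feeds = 2L,
                               signed = FALSE) {
  e <- as.data.table(epochs)[channel == "STO2"]
  f <- as.data.table(feeds)
  p <- as.data.table(piglets)
  setorder(f, piglet_id, t_h)
  f[, feed_index := seq_len(.N), by = piglet_id]
  f <- f[feed_index <= n_feeds]
  rows <- vector("list", nrow(f))
  for (i in seq_len(nrow(f))) {
    st <- feed_window_stat(e[piglet_id == f$piglet_id[i]], f$t_h[i],
                           signed = signed)
    if (!is.null(st)) {
      rows[[i]] <- data.table(piglet_id = f$piglet_id[i],
                              feed_index = f$feed_index[i], st)
    }
  }
  per_feed <- rbindlist(rows[!vapply(rows, is.null, logical(1))])
  if (!nrow(per_feed)) {
    return(list(per_feed = per_feed,
                per_piglet = data.table(), summary = data.table()))
  }
  per_piglet <- per_feed[, .(piglet_stat = mean(pct_change), n_feeds = .N),
                         by = piglet_id]
  per_piglet <- p[, .(piglet_id, group)][per_piglet, on = "piglet_id"]
  by_group <- per_piglet[, .(mean = mean(piglet_stat), sd = sd(piglet_stat),
                             n = .N), by = group]
  pooled <- per_piglet[group %in% NEC_GROUPS,
                       .(group = "NEC", mean = mean(piglet_stat),
                         sd = sd(piglet_stat), n = .N)]
  summary <- rbindlist(list(by_group, pooled), use.names = TRUE)
  list(per_feed = per_feed, per_piglet = per_piglet, summary = summary)
}
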