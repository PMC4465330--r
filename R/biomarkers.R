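## Plasma biomarker summaries and the tissue-densitometry correlation.

#' Group trajectory summary for a plasma analyte
#'
#' Per group and 6-hour draw time: mean, SEM and the number of animals still
#' contributing (draws stop at death, so attrition is implicit). Also
#' reports, per group, the pre-feed mean (all draws before `feed_h`) and the
#' post-feed peak mean (mean over animals of each animal's maximum draw at
#' or after `feed_h`).
#'
#' @param biomarkers the cohort's biomarker table.
#' @param piglets the cohort's piglet table.
#' @param analyte `"ifabp"` or `"saa"`.
#' @param feed_h first enteral feed time (default 48 h).
#' @return list with `grid` (group, t_h, mean, sem, n) and `excursion`
#'   (group, pre_feed_mean, post_feed_peak_mean, n_pre, n_animals_post).
#' @export
trajectory_summary <- function(biomarkers, piglets, analyte = c("ifabp", "saa"),
                               feed_h = 48) {
  analyte <- match.arg(analyte)
  col <- if (analyte == "ifabp") "ifabp_ng_ml" else "saa_ng_ml"
  b <- as.data.table(biomarkers)
  if (!col %in% names(b)) {
    nec_abort(sprintf("biomarker table has no '%s' column", col),
              "nec_schema_error")
  }
  p <- as.data.table(piglets)[, .(piglet_id, group)]
  b <- p[b, on = "piglet_id"]
  setnames(b, col, "value")
  grid <- b[, .(mean = mean(value),
                sem = if (.N >= 2L) sd(value) / sqrt(.N) else NA_real_,
                n = .N),
            by = .(group, t_h)]
  setorder(grid, group, t_h)
  pre <- b[t_h < feed_h, .(pre_feed_mean = mean(value), n_pre = .N), by = group]
  post <- b[t_h >= feed_h, .(peak = max(value)), by = .(group, piglet_id)]
  post <- post[, .(post_feed_peak_mean = mean(peak), n_animals_post = .N),
               by = group]
  list(grid = grid[],
       excursion = merge(pre, post, by = "group", all = TRUE)[])
}

#' Pooled post-feed analyte means, NEC vs No-NEC
#'
#' Pools every draw at or after the first feed across all animals of each
#' class (NEC = fulminant + non-fulminant) and reports the two class means;
#' pre-feed draws are excluded since pre-feed levels are at assay floor.
#' With `unit = "animal"`, animal means are pooled instead of raw draws.
#'
#' @inheritParams trajectory_summary
#' @param unit `"draw"` (default) or `"animal"`.
#' @return list with `nec_mean`, `no_nec_mean`, `n_nec`, `n_no_nec`, and
#'   `values` (per-class value vectors, for downstream testing).
#' @export
pooled_group_mean <- function(biomarkers, piglets, analyte = c("ifabp", "saa"),
                              feed_h = 48, unit = c("draw", "animal")) {
  analyte <- match.arg(analyte)
  unit <- match.arg(unit)
  col <- if (analyte == "ifabp") "ifabp_ng_ml" else "saa_ng_ml"
  b <- as.data.table(biomarkers)[t_h >= feed_h]
  p <- as.data.table(piglets)[, .(piglet_id, group)]
  b <- p[b, on = "piglet_id"]
  setnames(b, col, "value")
  if (unit == "animal") {
    b <- b[, .(value = mean(value)), by = .(piglet_id, group)]
  }
  b[, pool := ifelse(group %in% NEC_GROUPS, "NEC", "NO_NEC")]
  if (length(unique(b$pool)) < 2L) {
    nec_abort("both pooled classes must be non-empty", "nec_empty_class_error")
  }
  vals <- split(b$value, b$pool)
  list(nec_mean = mean(vals$NEC), no_nec_mean = mean(vals$NO_NEC),
       n_nec = length(vals$NEC), n_no_nec = length(vals$NO_NEC),
       values = vals)
}

#' Spearman correlation of jejunal densitometry with NEC score
#'
#' Rank correlation (mid-rank ties) between tissue I-FABP densitometry and
#' the ordinal histologic NEC score, with the two-sided asymptotic p-value.
#' Mucosal destruction releases I-FABP into plasma and strips it from
#' tissue, so the expected correlation is strongly negative.
#'
#' @param necropsy the cohort's necropsy table (`nec_score`,
#'   `densitometry_au`).
#' @return list with `rho`, `p_value`, `n`.
#' @export
densitometry_correlation <- function(necropsy) {
  n <- as.data.table(necropsy)
  if (nrow(n) < 3L) {
    nec_abort("need >= 3 necropsy records", "nec_validation_error")
  }
  if (var(n$nec_score) == 0 || var(n$densitometry_au) == 0) {
    nec_abort("no variation in nec_score or densitometry_au",
              "nec_degenerate_correlation_error")
  }
  ct <- suppressWarnings(
    cor.test(n$densitometry_au, n$nec_score, method = "spearman",
             exact = FALSE)
  )
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = nrow(n))
}
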