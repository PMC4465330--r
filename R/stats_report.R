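## Normality-gated group testing, the baseline summary table, the
## end-to-end report, and replicate-cohort summaries.

#' Normality-gated group comparison
#'
#' Implements the study's test-selection rule: Shapiro-Wilk on each group's
#' analysis-unit values; if every group is compatible with normality
#' (p > alpha) an ANOVA is used (repeated-measures with an animal error
#' stratum when `time` is supplied, one-way otherwise), else
#' Kruskal-Wallis. With exactly two groups a two-sample test (Welch t /
#' Wilcoxon) is used. Pairwise post-hoc comparisons (Tukey HSD on the
#' analysis-unit values, or pairwise Wilcoxon with Holm adjustment in the
#' non-parametric branch) are attached only when the global test is
#' significant and at least three groups are present.
#'
#' When `piglet` (and optionally `time`) are given, the analysis unit for
#' the gate and post-hoc step is the per-animal mean, not the raw repeated
#' observations.
#'
#' @param value numeric observations.
#' @param group group label per observation (2 or more levels, each with at
#'   least 3 analysis units).
#' @param piglet optional animal id per observation (repeated measures).
#' @param time optional time label per observation; triggers the
#'   repeated-measures ANOVA layout in the parametric branch.
#' @param alpha significance level for both the gate and the post-hoc
#'   trigger (default 0.05).
#' @return object of class `"nec_group_comparison"`: `groups`, `n`,
#'   `normality_p`, `method` (`RM_ANOVA_POSTHOC`, `ONEWAY_ANOVA_POSTHOC`,
#'   `KRUSKAL_WALLIS` or `TWO_SAMPLE`), `global_p`, `pairwise_p` (matrix or
#'   `NULL`), `alpha`.
#' @export
gated_group_test <- function(value, group, piglet = NULL, time = NULL,
                             alpha = 0.05) {
  group <- factor(group)
  if (nlevels(group) < 2L) {
    nec_abort("need at least two groups", "nec_insufficient_n_error")
  }
  ## analysis units: per-animal means when repeated measures are supplied
  if (!is.null(piglet)) {
    d <- data.table(value = value, group = group, piglet = piglet)
    units <- d[, .(value = mean(value), group = group[1L]), by = piglet]
    unit_value <- units$value
    unit_group <- units$group
  } else {
    unit_value <- value
    unit_group <- group
  }
  n_units <- table(unit_group)
  if (any(n_units < 3L)) {
    nec_abort("each group needs at least 3 analysis units",
              "nec_insufficient_n_error")
  }
  normality_p <- vapply(split(unit_value, unit_group), function(v) {
    if (length(unique(v)) < 3L) return(0)   # degenerate: treat as non-normal
    shapiro.test(v)$p.value
  }, numeric(1))
  parametric <- all(normality_p > alpha)
  k <- nlevels(group)
  pairwise <- NULL
  if (k == 2L) {
    method <- "TWO_SAMPLE"
    global_p <- if (parametric) {
      t.test(unit_value ~ unit_group)$p.value
    } else {
      suppressWarnings(wilcox.test(unit_value ~ unit_group)$p.value)
    }
  } else if (parametric) {
    if (!is.null(time) && !is.null(piglet)) {
      method <- "RM_ANOVA_POSTHOC"
      d <- data.frame(value = value, group = group,
                      time = factor(time), piglet = factor(piglet))
      fit <- aov(value ~ group + time + Error(piglet), data = d)
      tab <- summary(fit)[["Error: piglet"]][[1L]]
      global_p <- tab[["Pr(>F)"]][rownames(tab) == "group" |
                                    trimws(rownames(tab)) == "group"][1L]
    } else {
      method <- "ONEWAY_ANOVA_POSTHOC"
      global_p <- summary(aov(unit_value ~ unit_group))[[1L]][["Pr(>F)"]][1L]
    }
    if (!is.na(global_p) && global_p < alpha) {
      tk <- TukeyHSD(aov(unit_value ~ unit_group))$unit_group
      pairwise <- tk[, "p adj", drop = TRUE]
    }
  } else {
    method <- "KRUSKAL_WALLIS"
    global_p <- kruskal.test(unit_value, unit_group)$p.value
    if (global_p < alpha) {
      pw <- suppressWarnings(
        stats::pairwise.wilcox.test(unit_value, unit_group, p.adjust.method = "holm")
      )$p.value
      pairwise <- pw
    }
  }
  structure(
    list(groups = levels(group), n = as.integer(n_units),
         normality_p = normality_p, method = method, global_p = global_p,
         pairwise_p = pairwise, alpha = alpha),
    class = "nec_group_comparison"
  )
}

#' @export
print.nec_group_comparison <- function(x, ...) {
  cat(sprintf("<nec_group_comparison> %s | groups %s (n = %s) | global p = %.4g\n",
              x$method, paste(x$groups, collapse = "/"),
              paste(x$n, collapse = "/"), x$global_p))
  if (!is.null(x$pairwise_p)) {
    cat("  post-hoc pairwise p:\n")
    print(x$pairwise_p)
  }
  invisible(x)
}

#' Baseline summary table by NEC severity
#'
#' Mean +/- SD of birth weight, baseline hematocrit and the first-hour
#' baselines of heart rate, SpO2 and abdominal StO2 (A-NIRS) in each
#' severity group, with the gated group-test p-value per row.
#'
#' @param bundle a validated cohort bundle.
#' @param epochs optional precomputed [downsample_to_epochs()] output
#'   (computed from `bundle$vitals` when omitted).
#' @return list with `table` (display data.table: variable, one
#'   `mean +/- sd` column per group, p_value, method) and `stats`
#'   (per-variable numeric summaries and the `"nec_group_comparison"`).
#' @export
baseline_table <- function(bundle, epochs = NULL) {
  p <- bundle$piglets
  if (is.null(epochs)) epochs <- downsample_to_epochs(bundle$vitals)
  base <- compute_baseline(epochs)
  vars <- list(
    `Birth weight (g)` = p[, .(piglet_id, group, value = birth_weight_g)],
    `Baseline hematocrit (%)` = p[, .(piglet_id, group, value = baseline_hct)],
    `Baseline HR (bpm)` = base[channel == "HR"][p[, .(piglet_id, group)],
                                                on = "piglet_id", nomatch = NULL][
      , .(piglet_id, group, value = baseline)],
    `Baseline SpO2 (%)` = base[channel == "SPO2"][p[, .(piglet_id, group)],
                                                  on = "piglet_id", nomatch = NULL][
      , .(piglet_id, group, value = baseline)],
    `Baseline A-NIRS (%)` = base[channel == "STO2"][p[, .(piglet_id, group)],
                                                    on = "piglet_id", nomatch = NULL][
      , .(piglet_id, group, value = baseline)]
  )
  groups_present <- sort(unique(p$group))
  rows <- vector("list", length(vars))
  stats <- vector("list", length(vars))
  names(stats) <- names(vars)
  for (i in seq_along(vars)) {
    d <- vars[[i]][!is.na(value)]
    cmp <- gated_group_test(d$value, d$group)
    cells <- d[, .(cell = sprintf("%.1f ± %.1f", mean(value), sd(value)),
                   mean = mean(value), sd = sd(value), n = .N), by = group]
    row <- as.list(cells$cell)
    names(row) <- cells$group
    rows[[i]] <- data.table(
      variable = names(vars)[i],
      as.data.table(row)[, groups_present, with = FALSE],
      p_value = cmp$global_p, method = cmp$method
    )
    stats[[i]] <- list(summary = cells[], comparison = cmp)
  }
  list(table = rbindlist(rows, fill = TRUE), stats = stats)
}

report_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    nec_abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
              "nec_stage_error")
  })
}

#' Run the full analysis report on a cohort
#'
#' Executes preprocessing (epoching, baselines, trajectories), the
#' peri-prandial variability statistic, both screening ROCs, the biomarker
#' summaries and the necropsy correlation, and collects every headline
#' quantity into a machine-readable metrics list. Optionally writes the
#' tables and `metrics.json` to a directory.
#'
#' @param bundle a validated cohort bundle, or a directory path readable by
#'   [read_cohort()].
#' @param out_dir optional output directory for `table1.csv`,
#'   `trajectories.csv`, `variability.csv`, `roc_sto2.csv`,
#'   `roc_ifabp.csv`, `biomarker_summary.csv` and `metrics.json`.
#' @param sto2_window screening window passed to [screen_sto2()].
#' @param seed optional seed echoed into the metrics (provenance only; the
#'   report itself is deterministic given the cohort).
#' @return list with `metrics` (named list of headline numbers), `table1`,
#'   `trajectory`, `variability`, `screen_sto2`, `screen_ifabp`,
#'   `biomarkers`, `epochs`.
#' @export
run_report <- function(bundle, out_dir = NULL, sto2_window = c(0, 48),
                       seed = NULL) {
  if (is.character(bundle)) bundle <- report_stage("cohort_io", read_cohort(bundle))
  for (nm in names(COHORT_FILES)) {
    if (is.null(bundle[[nm]]) || !nrow(bundle[[nm]])) {
      nec_abort(sprintf("stage '%s' failed: table '%s' is missing or empty",
                        nm, nm), "nec_stage_error")
    }
  }
  p <- bundle$piglets
  counts <- table(factor(p$group, levels = GROUPS))
  n_nec <- sum(counts[NEC_GROUPS])
  epochs <- report_stage("preprocess", downsample_to_epochs(bundle$vitals))
  tab1 <- report_stage("preprocess", baseline_table(bundle, epochs))
  traj <- report_stage("preprocess", group_trajectory(epochs, p))
  pooled_sto2 <- epochs[channel == "STO2" & !is.na(mean_value)][
    p[, .(piglet_id, group)], on = "piglet_id", nomatch = NULL][
      , .(mean = mean(mean_value), n_epochs = .N), by = group]
  variab <- report_stage("periprandial",
                         cohort_variability(epochs, bundle$feeds, p))
  scr_sto2 <- report_stage("diagnostics",
                           screen_sto2(epochs, p, window_h = sto2_window))
  scr_ifabp <- report_stage("diagnostics", screen_ifabp(bundle$biomarkers, p))
  bio_traj <- report_stage("biomarkers",
                           trajectory_summary(bundle$biomarkers, p, "ifabp"))
  bio_pool <- report_stage("biomarkers",
                           pooled_group_mean(bundle$biomarkers, p, "ifabp"))
  rho <- report_stage("biomarkers", densitometry_correlation(bundle$necropsy))

  gm <- function(g) pooled_sto2[group == g, mean]
  exc <- bio_traj$excursion
  vsum <- function(g) variab$summary[group == g, mean]
  metrics <- list(
    schema_version = "1.0",
    seed = seed,
    n_piglets = nrow(p),
    group_counts = as.list(counts),
    nec_incidence_pct = as.integer(round(100 * n_nec / nrow(p))),
    sto2_pooled_mean = list(F_NEC = gm("F_NEC"), NF_NEC = gm("NF_NEC"),
                            NO_NEC = gm("NO_NEC")),
    variability_pct = list(NEC = vsum("NEC"), NO_NEC = vsum("NO_NEC")),
    sto2_cutoff = scr_sto2$roc$chosen_cutoff,
    sto2_sens = scr_sto2$confusion$sens,
    sto2_spec = scr_sto2$confusion$spec,
    sto2_auc = scr_sto2$roc$auc,
    ifabp_cutoff = scr_ifabp$roc$chosen_cutoff,
    ifabp_sens = scr_ifabp$confusion$sens,
    ifabp_spec = scr_ifabp$confusion$spec,
    ifabp_auc = scr_ifabp$roc$auc,
    ifabp_pooled_nec = bio_pool$nec_mean,
    ifabp_pooled_no_nec = bio_pool$no_nec_mean,
    ifabp_fnec_pre_feed = exc[group == "F_NEC", pre_feed_mean],
    ifabp_fnec_peak = exc[group == "F_NEC", post_feed_peak_mean],
    densitometry_rho = rho$rho,
    densitometry_p = rho$p_value
  )
  out <- list(metrics = metrics, table1 = tab1, trajectory = traj,
              variability = variab, screen_sto2 = scr_sto2,
              screen_ifabp = scr_ifabp,
              biomarkers = list(trajectory = bio_traj, pooled = bio_pool,
                                densitometry = rho),
              epochs = epochs)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    fwrite(tab1$table, file.path(out_dir, "table1.csv"))
    fwrite(traj, file.path(out_dir, "trajectories.csv"))
    fwrite(variab$per_piglet, file.path(out_dir, "variability.csv"))
    fwrite(data.table(threshold = scr_sto2$roc$thresholds,
                      sens = scr_sto2$roc$sens, spec = scr_sto2$roc$spec),
           file.path(out_dir, "roc_sto2.csv"))
    fwrite(data.table(threshold = scr_ifabp$roc$thresholds,
                      sens = scr_ifabp$roc$sens, spec = scr_ifabp$roc$spec),
           file.path(out_dir, "roc_ifabp.csv"))
    fwrite(bio_traj$grid, file.path(out_dir, "biomarker_summary.csv"))
    jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' Headline statistics over replicate simulated cohorts
#'
#' Simulates one cohort per seed under the default configuration (or a
#' caller-supplied configuration factory) and returns the per-replicate
#' headline quantities used for parameter-recovery checks: pooled StO2
#' epoch means per group, the fulminant first-hour StO2 baseline,
#' peri-prandial variability (pooled NEC and No-NEC), both Youden cutoffs,
#' pooled post-feed I-FABP means, the fulminant pre-feed mean and
#' per-animal peak mean, and the densitometry-score Spearman rho.
#'
#' @param seeds integer vector; one replicate per seed.
#' @param config_fn function(seed) returning a [sim_config()]; defaults to
#'   the study-design configuration.
#' @return data.table with one row per replicate.
#' @export
cohort_replicate_stats <- function(seeds,
                                   config_fn = function(s) sim_config(seed = s)) {
  rows <- vector("list", length(seeds))
  for (i in seq_along(seeds)) {
    cohort <- simulate_cohort(config_fn(seeds[i]))
    p <- cohort$piglets
    epochs <- downsample_to_epochs(cohort$vitals)
    sto2 <- epochs[channel == "STO2" & !is.na(mean_value)][
      p[, .(piglet_id, group)], on = "piglet_id", nomatch = NULL]
    pooled <- sto2[, .(mean = mean(mean_value)), by = group]
    base <- compute_baseline(epochs[channel == "STO2"])
    base <- p[, .(piglet_id, group)][base, on = "piglet_id"]
    variab <- cohort_variability(epochs, cohort$feeds, p)
    scr_s <- screen_sto2(epochs, p)
    scr_i <- screen_ifabp(cohort$biomarkers, p)
    pool <- pooled_group_mean(cohort$biomarkers, p, "ifabp")
    exc <- trajectory_summary(cohort$biomarkers, p, "ifabp")$excursion
    rho <- densitometry_correlation(cohort$necropsy)
    rows[[i]] <- data.table(
      seed = seeds[i],
      sto2_mean_f = pooled[group == "F_NEC", mean],
      sto2_mean_nf = pooled[group == "NF_NEC", mean],
      sto2_mean_no = pooled[group == "NO_NEC", mean],
      sto2_baseline_f = base[group == "F_NEC", mean(baseline)],
      variability_nec = variab$summary[group == "NEC", mean],
      variability_no = variab$summary[group == "NO_NEC", mean],
      sto2_cutoff = scr_s$roc$chosen_cutoff,
      ifabp_cutoff = scr_i$roc$chosen_cutoff,
      ifabp_pooled_nec = pool$nec_mean,
      ifabp_pooled_no = pool$no_nec_mean,
      ifabp_fnec_peak = exc[group == "F_NEC", post_feed_peak_mean],
      densitometry_rho = rho$rho
    )
    rm(cohort, epochs, sto2)
    gc(verbose = FALSE)
  }
  rbindlist(rows)
}
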