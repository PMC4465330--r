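## ROC construction and screening-cutoff selection.
##
## Both screening variables are direction-specific: low abdominal StO2 flags
## NEC (decision rule score < t) and high plasma I-FABP flags NEC (score >
## t). The empirical ROC is evaluated at every distinct score, the area by
## trapezoid, and the operating cutoff by the Youden index J = sens + spec -
## 1 (ties resolved toward sensitivity, then toward the smaller-magnitude
## threshold).

#' Empirical ROC curve with Youden cutoff
#'
#' @param scores numeric scores (finite).
#' @param labels logical (or coercible) vector, `TRUE` = positive class
#'   (progresses to NEC). Both classes must be present.
#' @param orientation `"lower"` (score < t is a positive call; StO2) or
#'   `"higher"` (score > t; I-FABP).
#' @return object of class `"nec_roc"`: `thresholds` (sorted distinct
#'   scores), `sens`, `spec`, `auc`, `chosen_cutoff`, `sens_at_cutoff`,
#'   `spec_at_cutoff`, `orientation`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels, orientation = c("lower", "higher")) {
  orientation <- match.arg(orientation)
  labels <- as.logical(labels)
  if (anyNA(scores) || any(!is.finite(scores))) {
    nec_abort("scores must be finite", "nec_validation_error")
  }
  if (anyNA(labels)) nec_abort("labels must not be NA", "nec_validation_error")
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    nec_abort("both classes must be present to build a ROC curve",
              "nec_degenerate_labels_error")
  }
  u <- sort(unique(scores))
  cp <- cumsum(tabulate(findInterval(scores[labels], u), nbins = length(u)))
  cn <- cumsum(tabulate(findInterval(scores[!labels], u), nbins = length(u)))
  pos_below <- c(0, head(cp, -1L))   # #pos strictly below each threshold
  neg_below <- c(0, head(cn, -1L))
  if (orientation == "lower") {
    sens <- pos_below / n_pos          # called positive: score < t
    spec <- (n_neg - neg_below) / n_neg
  } else {
    sens <- (n_pos - cp) / n_pos       # called positive: score > t
    spec <- cn / n_neg
  }
  ## trapezoid AUC over the full curve including the (0,0) and (1,1) ends
  fpr <- c(0, sort(1 - spec), 1)
  tpr <- c(0, sort(sens), 1)
  auc <- sum(diff(fpr) * (head(tpr, -1L) + tail(tpr, -1L)) / 2)
  j <- sens + spec - 1
  best <- which(j > max(j) - 1e-12)
  best <- best[sens[best] > max(sens[best]) - 1e-12]
  best <- best[which.min(abs(u[best]))]
  structure(
    list(thresholds = u, sens = sens, spec = spec, auc = auc,
         chosen_cutoff = u[best], sens_at_cutoff = sens[best],
         spec_at_cutoff = spec[best], orientation = orientation,
         n_pos = n_pos, n_neg = n_neg),
    class = "nec_roc"
  )
}

#' @export
print.nec_roc <- function(x, ...) {
  cat(sprintf("<nec_roc> %s-is-positive | AUC %.3f | Youden cutoff %.4g (sens %.3f, spec %.3f) | %d pos / %d neg\n",
              x$orientation, x$auc, x$chosen_cutoff, x$sens_at_cutoff,
              x$spec_at_cutoff, x$n_pos, x$n_neg))
  invisible(x)
}

#' Sensitivity/specificity and confusion counts at a fixed threshold
#'
#' @inheritParams roc_curve
#' @param threshold decision threshold (any finite value, not necessarily an
#'   observed score).
#' @return list with `threshold`, `sens`, `spec`, and the confusion counts
#'   `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_at <- function(scores, labels, threshold,
                         orientation = c("lower", "higher")) {
  orientation <- match.arg(orientation)
  labels <- as.logical(labels)
  called <- if (orientation == "lower") scores < threshold else scores > threshold
  tp <- sum(called & labels)
  fp <- sum(called & !labels)
  fn <- sum(!called & labels)
  tn <- sum(!called & !labels)
  list(threshold = threshold,
       sens = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       spec = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Epoch-level abdominal StO2 screening
#'
#' Every non-missing 1-minute StO2 epoch inside the screening window is a
#' score labeled by its animal's eventual NEC status (fulminant or
#' non-fulminant = positive); low values call NEC. The window defaults to
#' hours 0-48, the pre-symptomatic, pre-feed period. With `unit =
#' "animal"`, each animal contributes its mean epoch value instead.
#'
#' @param epochs cohort epochs ([downsample_to_epochs()]).
#' @param piglets the cohort's piglet table.
#' @param window_h two-element window `[from, to)` in hours.
#' @param threshold optional forced cutoff; when given, sens/spec are
#'   reported at it instead of the Youden choice.
#' @param unit `"epoch"` (default) or `"animal"`.
#' @return list with `roc` (a `"nec_roc"`), `confusion` (at the chosen or
#'   forced cutoff), `unit`, `window_h`, `n_scores`.
#' @export
screen_sto2 <- function(epochs, piglets, window_h = c(0, 48),
                        threshold = NULL, unit = c("epoch", "animal")) {
  unit <- match.arg(unit)
  e <- as.data.table(epochs)[channel == "STO2" & !is.na(mean_value) &
                               epoch_start_h >= window_h[1] &
                               epoch_start_h < window_h[2]]
  if (!nrow(e)) {
    nec_abort("no StO2 epochs in the screening window", "nec_empty_input_error")
  }
  if (unit == "animal") {
    e <- e[, .(mean_value = mean(mean_value)), by = piglet_id]
  }
  p <- as.data.table(piglets)
  lab <- p$group[match(e$piglet_id, p$piglet_id)] %in% NEC_GROUPS
  roc <- roc_curve(e$mean_value, lab, orientation = "lower")
  cut <- threshold %||% roc$chosen_cutoff
  list(roc = roc, confusion = confusion_at(e$mean_value, lab, cut, "lower"),
       unit = unit, window_h = window_h, n_scores = nrow(e))
}

#' Sample-level plasma I-FABP screening
#'
#' Every I-FABP draw at or after the first feed (t >= `min_t_h`) is a score
#' labeled by its animal's eventual NEC status; high values call NEC. With
#' `unit = "animal"`, each animal contributes its peak post-feed value.
#'
#' @param biomarkers the cohort's biomarker table.
#' @param piglets the cohort's piglet table.
#' @param min_t_h earliest draw time included (default 48 h, the first
#'   feed).
#' @param threshold optional forced cutoff (ng/mL).
#' @param unit `"sample"` (default) or `"animal"`.
#' @return list as in [screen_sto2()].
#' @export
screen_ifabp <- function(biomarkers, piglets, min_t_h = 48,
                         threshold = NULL, unit = c("sample", "animal")) {
  unit <- match.arg(unit)
  b <- as.data.table(biomarkers)[t_h >= min_t_h]
  if (!nrow(b)) {
    nec_abort("no post-feed I-FABP draws available", "nec_empty_input_error")
  }
  scores <- if (unit == "animal") {
    b[, .(score = max(ifabp_ng_ml)), by = piglet_id]
  } else {
    b[, .(piglet_id, score = ifabp_ng_ml)]
  }
  p <- as.data.table(piglets)
  lab <- p$group[match(scores$piglet_id, p$piglet_id)] %in% NEC_GROUPS
  roc <- roc_curve(scores$score, lab, orientation = "higher")
  cut <- threshold %||% roc$chosen_cutoff
  list(roc = roc, confusion = confusion_at(scores$score, lab, cut, "higher"),
       unit = unit, min_t_h = min_t_h, n_scores = nrow(scores))
}
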