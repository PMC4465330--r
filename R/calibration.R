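## NIRS validation-study calibration.
##
## Ground truth for the abdominal probe is the weighted arterio-venous
## composite 0.3*SaO2 + 0.7*ScvO2 from CO-oximetry of simultaneous arterial
## and central-venous draws at four FiO2 plateaus. The monitor reading is
## regressed on the composite (shared slope, meconium-stratum intercepts)
## and the fitted relation inverted to correct raw readings.

#' Weighted arterio-venous composite reference saturation
#'
#' `0.3 * SaO2 + 0.7 * ScvO2`, the splanchnic-bed mix the NIRS optode
#' interrogates (30% arterial, 70% venous blood volume).
#'
#' @param sao2,scvo2 arterial / central-venous functional saturation in
#'   percent, each in `[0, 100]`. Vectorized.
#' @return composite reference StO2 in percent.
#' @export
composite_reference <- function(sao2, scvo2) {
  if (any(sao2 < 0 | sao2 > 100, na.rm = TRUE) ||
      any(scvo2 < 0 | scvo2 > 100, na.rm = TRUE)) {
    nec_abort("sao2 and scvo2 must lie in [0,100]", "nec_domain_error")
  }
  0.3 * sao2 + 0.7 * scvo2
}

#' Fit the plateau calibration model
#'
#' Ordinary least squares of the measured monitor StO2 on the composite
#' reference. With both meconium strata present, a shared slope with
#' stratum-specific intercepts is fitted (meconium is a chromophore offset);
#' with one stratum, a simple line. The reported Pearson r is
#' `cor(measured, fitted)`, so `r_squared = pearson_r^2` equals the model
#' R-squared in both layouts.
#'
#' @param plateaus data.frame with `sao2`, `scvo2`, `measured_sto2` and
#'   optionally `meconium_present` (logical; absent = all clear).
#' @return object of class `"nec_calfit"`: `slope`, `intercept` (named per
#'   stratum: `clear`, and `meconium` when fitted), `pearson_r`,
#'   `r_squared`, `n_points`.
#' @export
fit_calibration <- function(plateaus) {
  d <- as.data.table(plateaus)
  if (!"meconium_present" %in% names(d)) d[, meconium_present := FALSE]
  d[, ref := composite_reference(sao2, scvo2)]
  strata <- split(seq_len(nrow(d)), d$meconium_present)
  if (any(vapply(strata, length, integer(1)) < 3L)) {
    nec_abort("each meconium stratum needs >= 3 plateaus", "nec_validation_error")
  }
  if (var(d$ref) < 1e-12) {
    nec_abort("composite reference has zero variance; calibration fit is singular",
              "nec_singular_fit_error")
  }
  two_strata <- length(strata) == 2L
  fit <- if (two_strata) {
    lm(measured_sto2 ~ ref + meconium_present, data = d)
  } else {
    lm(measured_sto2 ~ ref, data = d)
  }
  cf <- coef(fit)
  intercept <- c(clear = unname(cf["(Intercept)"]))
  if (two_strata) {
    intercept["meconium"] <- unname(cf["(Intercept)"] + cf["meconium_presentTRUE"])
  }
  r <- cor(d$measured_sto2, fitted(fit))
  structure(
    list(slope = unname(cf["ref"]), intercept = intercept,
         pearson_r = r, r_squared = r^2, n_points = nrow(d)),
    class = "nec_calfit"
  )
}

#' @export
print.nec_calfit <- function(x, ...) {
  cat(sprintf("<nec_calfit> slope %.4f, intercept %s | r = %.4f, R^2 = %.4f (n = %d)\n",
              x$slope,
              paste(sprintf("%s %.3f", names(x$intercept), x$intercept),
                    collapse = ", "),
              x$pearson_r, x$r_squared, x$n_points))
  invisible(x)
}

#' Apply a calibration fit to raw monitor readings
#'
#' Inverts the fitted line: `(raw - intercept) / slope`, clamped to
#' `[0, 100]` percent.
#'
#' @param fit a `"nec_calfit"` object.
#' @param raw_sto2 raw monitor readings (percent). Vectorized.
#' @param stratum `"clear"` (default) or `"meconium"`; selects the
#'   intercept.
#' @return corrected StO2 in percent.
#' @export
apply_calibration <- function(fit, raw_sto2, stratum = "clear") {
  if (!inherits(fit, "nec_calfit")) {
    nec_abort("fit must be a nec_calfit object", "nec_validation_error")
  }
  if (abs(fit$slope) < 1e-12) {
    nec_abort("calibration slope is zero; cannot invert", "nec_singular_fit_error")
  }
  if (!stratum %in% names(fit$intercept)) {
    nec_abort(sprintf("no '%s' intercept in this fit", stratum),
              "nec_validation_error")
  }
  corrected <- (raw_sto2 - fit$intercept[[stratum]]) / fit$slope
  pmin(pmax(corrected, 0), 100)
}
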