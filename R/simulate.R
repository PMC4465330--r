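## Synthetic premature-piglet cohort generator.
##
## Each piglet gets group-specific piecewise-linear mean trajectories with a
## per-animal baseline offset (between-animal variation), stationary AR(1)
## noise on the 2-second sampling grid, and, for abdominal StO2, a transient
## post-feed dip (exponential recovery) proportional to the pre-feed level.
## Emitted numbers are quantized to short decimals (t_h to 1e-7 h, values to
## 1e-4) so the CSV round trip is exact.

## fast decimal quantization (round(x, d) is slow on long vectors)
round_t <- function(t) round(t * 1e7) / 1e7
round_v <- function(x) round(x * 1e4) / 1e4

## evaluate a knot curve at times t (constant extrapolation beyond knots)
eval_knots <- function(knots, t) {
  approx(knots[, "t_h"], knots[, "level"], xout = t, rule = 2)$y
}

## end of a piglet's recording: strictly before death, else study end
recording_end <- function(piglet, study_end_h) {
  if (is.na(piglet$death_h)) study_end_h else min(piglet$death_h, study_end_h)
}

#' Simulate one vitals channel for one piglet
#'
#' Produces the 2-second stream `mean curve + AR(1) noise + feed dips`
#' clamped to channel bounds and truncated strictly before death. The feed
#' dip (StO2 channel in the default configuration) subtracts
#' `amp/100 * pre-feed level * exp(-(t - t_feed)/tau)` after each feed, i.e.
#' a transient deflection recovering on the `feed_dip_tau_min` time scale
#' within the 15-minute post-feed window.
#'
#' Uses the ambient RNG stream: seed it (or call via [simulate_cohort()]) for
#' reproducibility.
#'
#' @param piglet one-row data.frame/list with `piglet_id`, `group`, `death_h`.
#' @param channel `"HR"`, `"SPO2"` or `"STO2"`.
#' @param params channel parameter list (see `cfg$vitals[[channel]]`).
#' @param feeds_t numeric vector of this piglet's feed times (hours).
#' @param cfg a [sim_config()] object (timing fields are read from it).
#' @param baseline_offset per-animal curve offset; if `NULL`, drawn
#'   `N(0, baseline_sd)`.
#' @return data.table(piglet_id, channel, t_h, value).
#' @export
simulate_vitals_channel <- function(piglet, channel, params, feeds_t, cfg,
                                    baseline_offset = NULL) {
  end_h <- recording_end(piglet, cfg$study_end_h)
  per_h <- 3600 / cfg$sample_period_s
  n <- floor(end_h * per_h - 1e-9) + 1L   # samples at k/per_h < end_h
  t <- (seq_len(n) - 1L) / per_h
  gp <- params$groups[[piglet$group]]
  if (is.null(baseline_offset)) {
    baseline_offset <- rnorm(1L, 0, gp$baseline_sd)
  }
  mu <- eval_knots(gp$knots, t) + baseline_offset
  x <- mu
  if (params$noise_sd > 0) {
    phi <- params$ar1_phi
    innov_sd <- params$noise_sd * sqrt(1 - phi^2)
    init <- rnorm(1L, 0, params$noise_sd)
    x <- x + as.numeric(filter(rnorm(n, 0, innov_sd), phi,
                               method = "recursive", init = init))
  }
  if (gp$feed_dip_amp_pct > 0 && length(feeds_t)) {
    tau_h <- params$feed_dip_tau_min / 60
    for (tf in feeds_t[feeds_t < end_h]) {
      pre_level <- eval_knots(gp$knots, tf) + baseline_offset
      amp <- gp$feed_dip_amp_pct / 100 * pre_level
      span <- findInterval(c(tf, tf + 8 * tau_h), t)
      if (span[2] > span[1]) {
        idx <- (span[1] + 1L):span[2]
        x[idx] <- x[idx] - amp * exp(-(t[idx] - tf) / tau_h)
      }
    }
  }
  bounds <- channel_bounds(channel)
  x <- pmin(pmax(x, bounds[1]), bounds[2])
  out <- list(piglet_id = rep(piglet$piglet_id, n),
              channel = rep(channel, n),
              t_h = round_t(t), value = round_v(x))
  setDT(out)
  out
}

## deterministic I-FABP mean kinetic: flat baseline, then linear rise toward
## a plateau starting rise_onset_h after the first feed
ifabp_mean_curve <- function(t, kin, first_feed_h) {
  t0 <- first_feed_h + kin$rise_onset_h
  pmin(kin$plateau_peak,
       kin$ifabp_baseline + kin$rise_rate * pmax(0, t - t0))
}

#' Simulate the 6-hourly biomarker draws for one piglet
#'
#' I-FABP follows the group kinetic (baseline until `rise_onset_h` after the
#' first feed, then a linear rise capped at `plateau_peak`), with the final
#' pre-mortem draw of a dying piglet attenuated by
#' `premortem_decay_fraction` (the exhaustion/venous-congestion effect). SAA
#' rises identically in all groups after feeds begin. Multiplicative
#' mean-one lognormal assay noise; draws stop at death.
#'
#' @inheritParams simulate_vitals_channel
#' @param kinetics biomarker kinetics list (see `cfg$biomarkers`).
#' @return data.table(piglet_id, t_h, ifabp_ng_ml, saa_ng_ml).
#' @export
simulate_biomarkers <- function(piglet, kinetics, cfg) {
  end_h <- if (is.na(piglet$death_h)) cfg$study_end_h else piglet$death_h
  t <- seq(0, cfg$study_end_h, by = cfg$draw_interval_h)
  t <- t[t <= end_h + 1e-9]
  kin <- kinetics$groups[[piglet$group]]
  mu <- ifabp_mean_curve(t, kin, cfg$first_feed_h)
  if (!is.na(piglet$death_h) && length(mu)) {
    mu[length(mu)] <- mu[length(mu)] * (1 - kin$premortem_decay_fraction)
  }
  s <- kinetics$noise_sdlog
  ifabp <- if (s > 0) mu * exp(rnorm(length(t), -s^2 / 2, s)) else mu
  saa_mu <- kinetics$saa$baseline +
    kinetics$saa$slope_per_h * pmax(0, t - cfg$first_feed_h)
  ss <- kinetics$saa$noise_sdlog
  saa <- if (ss > 0) saa_mu * exp(rnorm(length(t), -ss^2 / 2, ss)) else saa_mu
  data.table(piglet_id = piglet$piglet_id, t_h = t,
             ifabp_ng_ml = round(pmax(ifabp, 0), 4),
             saa_ng_ml = round(pmax(saa, 0), 4))
}

#' Simulate the necropsy record for one piglet
#'
#' Draws the histologic NEC score from the group-specific ordinal
#' distribution (No-NEC in 0..1, non-fulminant 2..4, fulminant 4..6) and
#' couples jejunal I-FABP densitometry inversely to it:
#' `base_au - slope_au_per_score * score + N(0, noise_sd)`, floored at 0.
#'
#' @inheritParams simulate_vitals_channel
#' @param params necropsy parameter list (see `cfg$necropsy`).
#' @return data.table(piglet_id, nec_score, densitometry_au).
#' @export
simulate_necropsy <- function(piglet, params) {
  probs <- params$score_probs[[piglet$group]]
  score <- as.integer(sample(names(probs), 1L, prob = probs))
  au <- params$base_au - params$slope_au_per_score * score +
    rnorm(1L, 0, params$noise_sd)
  data.table(piglet_id = piglet$piglet_id, nec_score = score,
             densitometry_au = round(max(au, 0), 2))
}

#' Simulate a NIRS validation plateau table
#'
#' Each piglet is held at four inspired-oxygen plateaus
#' (FiO2 0.08, 0.21, 0.60, 1.0); arterial saturation is drawn per plateau
#' (order-enforced so higher FiO2 gives higher SaO2), central-venous
#' saturation sits an arteriovenous gap below it, and the monitor reading is
#' `slope * (0.3 SaO2 + 0.7 ScvO2) + intercept (+ meconium offset) + noise`.
#'
#' @param n_piglets number of validation piglets (default 5).
#' @param params validation parameter list; defaults to
#'   `sim_config()$validation`.
#' @param noise_sd override for the monitor noise SD (percentage points).
#' @param meconium logical; if `TRUE` all rows are flagged
#'   `meconium_present` and receive `params$meconium_offset`.
#' @return data.table(piglet_id, fio2, sao2, scvo2, measured_sto2,
#'   meconium_present), 4 rows per piglet, ordered by piglet then FiO2.
#' @export
simulate_validation_plateaus <- function(n_piglets = 5L,
                                         params = sim_config()$validation,
                                         noise_sd = NULL,
                                         meconium = FALSE) {
  if (n_piglets < 1) nec_abort("n_piglets must be >= 1", "nec_config_error")
  if (!is.null(noise_sd)) params$noise_sd <- noise_sd
  ord <- order(params$fio2)
  out <- vector("list", n_piglets)
  for (i in seq_len(n_piglets)) {
    sao2 <- rnorm(length(params$fio2), params$sao2_mean, params$sao2_sd)
    ## enforce the FiO2 ordering invariant within each piglet
    sao2 <- sort(sao2)[rank(params$sao2_mean, ties.method = "first")]
    sao2 <- pmin(pmax(sao2, 1), 100)
    gap <- pmax(rnorm(length(sao2), params$av_gap_mean, params$av_gap_sd),
                params$av_gap_min)
    scvo2 <- pmax(sao2 - gap, 0.5)
    ref <- composite_reference(sao2, scvo2)
    meas <- params$slope * ref + params$intercept +
      (if (meconium) params$meconium_offset else 0) +
      rnorm(length(ref), 0, params$noise_sd)
    out[[i]] <- data.table(
      piglet_id = sprintf("V%02d", i),
      fio2 = params$fio2[ord], sao2 = round(sao2[ord], 2),
      scvo2 = round(scvo2[ord], 2),
      measured_sto2 = round(pmin(pmax(meas[ord], 0), 100), 2),
      meconium_present = meconium
    )
  }
  rbindlist(out)
}

simulate_piglets <- function(cfg) {
  groups <- rep(GROUPS, times = cfg$n_per_group[GROUPS])
  n <- length(groups)
  cens <- cfg$censoring
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    g <- groups[i]
    a <- cfg$anthro[[g]]
    symptom <- NA_real_
    death <- NA_real_
    if (g == "F_NEC") {
      symptom <- runif(1, cens$f_symptom_range_h[1], cens$f_symptom_range_h[2])
      death <- runif(1, max(cens$f_death_range_h[1], symptom),
                     cens$f_death_range_h[2])
    } else if (g == "NF_NEC") {
      symptom <- runif(1, cens$nf_symptom_range_h[1], cens$nf_symptom_range_h[2])
      if (runif(1) >= cens$nf_survival_prob) {
        death <- min(cfg$study_end_h,
                     symptom + runif(1, cens$nf_death_delay_range_h[1],
                                     cens$nf_death_delay_range_h[2]))
      }
    }
    rows[[i]] <- data.table(
      piglet_id = sprintf("P%02d", i),
      litter_id = sprintf("L%d", ((i - 1L) %% cfg$n_litters) + 1L),
      birth_weight_g = round(max(rnorm(1, a$weight_mean, a$weight_sd), 300), 1),
      baseline_hct = round(min(max(rnorm(1, a$hct_mean, a$hct_sd), 5), 60), 1),
      group = g,
      symptom_onset_h = round(symptom, 3),
      death_h = round(death, 3)
    )
  }
  rbindlist(rows)
}

#' Simulate a complete monitored cohort
#'
#' Generates, under `config$seed`, the five cohort tables: piglet records
#' with group-specific anthropometrics and censoring times, 2-second vitals
#' streams for HR, SpO2 and abdominal StO2, the 3-hourly enteral feed
#' schedule from 48 h (feeds stop at death), 6-hourly biomarker draws, and
#' one necropsy record per piglet. The output passes [validate_cohort()] and
#' is byte-identical for identical configurations.
#'
#' @param config a [sim_config()] object.
#' @return a validated `"nec_cohort"` bundle.
#' @export
simulate_cohort <- function(config = sim_config()) {
  if (!inherits(config, "nec_sim_config")) {
    nec_abort("config must be built with sim_config()", "nec_config_error")
  }
  set.seed(config$seed)
  piglets <- simulate_piglets(config)
  feed_grid <- seq(config$first_feed_h, config$study_end_h - config$feed_interval_h,
                   by = config$feed_interval_h)
  n <- nrow(piglets)
  vitals <- vector("list", n * length(CHANNELS))
  feeds <- vector("list", n)
  biomarkers <- vector("list", n)
  necropsy <- vector("list", n)
  for (i in seq_len(n)) {
    p <- as.list(piglets[i])
    end_h <- recording_end(p, config$study_end_h)
    ft <- feed_grid[feed_grid < end_h]
    if (length(ft)) {
      feeds[[i]] <- data.table(piglet_id = p$piglet_id, t_h = ft,
                               volume_ml_per_kg = config$feed_volume_ml_per_kg)
    }
    for (k in seq_along(CHANNELS)) {
      ch <- CHANNELS[k]
      vitals[[(i - 1L) * length(CHANNELS) + k]] <-
        simulate_vitals_channel(p, ch, config$vitals[[ch]], ft, config)
    }
    biomarkers[[i]] <- simulate_biomarkers(p, config$biomarkers, config)
    necropsy[[i]] <- simulate_necropsy(p, config$necropsy)
  }
  nec_cohort(
    piglets = piglets,
    vitals = rbindlist(vitals),
    feeds = rbindlist(feeds[!vapply(feeds, is.null, logical(1))]),
    biomarkers = rbindlist(biomarkers),
    necropsy = rbindlist(necropsy)
  )
}
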