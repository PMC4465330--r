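## Shared fixtures, all built in code.

## a 2-second vitals stream for one piglet/channel
make_stream <- function(values, piglet_id = "P01", channel = "STO2",
                        start_h = 0) {
  n <- length(values)
  data.table::data.table(
    piglet_id = piglet_id, channel = channel,
    t_h = round(start_h + (seq_len(n) - 1) / 1800, 7),
    value = values
  )
}

## minimal piglet table
make_piglets <- function(ids, groups, death_h = NA_real_,
                         symptom_onset_h = NA_real_) {
  data.table::data.table(
    piglet_id = ids,
    litter_id = "L1",
    birth_weight_g = 1000,
    baseline_hct = 20,
    group = groups,
    symptom_onset_h = symptom_onset_h,
    death_h = death_h
  )
}

## a small, fully valid, randomized bundle for round-trip properties
random_bundle <- function(seed) {
  set.seed(seed)
  n <- sample(2:5, 1)
  groups <- sample(c("F_NEC", "NF_NEC", "NO_NEC"), n, replace = TRUE)
  groups[1] <- "NO_NEC"   # guarantee at least one No-NEC animal
  ids <- sprintf("P%02d", seq_len(n))
  death <- ifelse(groups == "F_NEC", round(runif(n, 55, 66), 3), NA_real_)
  symptom <- ifelse(groups == "F_NEC", round(runif(n, 49, 54), 3), NA_real_)
  piglets <- data.table::data.table(
    piglet_id = ids, litter_id = sample(c("L1", "L2"), n, replace = TRUE),
    birth_weight_g = round(runif(n, 800, 1400), 1),
    baseline_hct = round(runif(n, 15, 30), 1),
    group = groups, symptom_onset_h = symptom, death_h = death
  )
  vitals <- data.table::rbindlist(lapply(seq_len(n), function(i) {
    end <- min(death[i], 2, na.rm = TRUE)
    k <- floor(end * 1800)
    data.table::rbindlist(lapply(c("HR", "SPO2", "STO2"), function(ch) {
      v <- if (ch == "HR") runif(k, 120, 200) else runif(k, 50, 95)
      make_stream(round(v, 4), ids[i], ch)
    }))
  }))
  feeds <- data.table::data.table(
    piglet_id = ids, t_h = 48, volume_ml_per_kg = 12
  )[is.na(death) | death > 48]
  biomarkers <- data.table::rbindlist(lapply(seq_len(n), function(i) {
    t <- seq(0, 96, by = 6)
    t <- t[is.na(death[i]) | t <= death[i]]
    data.table::data.table(piglet_id = ids[i], t_h = t,
                           ifabp_ng_ml = round(runif(length(t), 0, 2), 4),
                           saa_ng_ml = round(runif(length(t), 0, 50), 4))
  }))
  necropsy <- data.table::data.table(
    piglet_id = ids,
    nec_score = ifelse(groups == "NO_NEC", sample(0:1, n, TRUE),
                       ifelse(groups == "F_NEC", sample(4:6, n, TRUE),
                              sample(2:4, n, TRUE))),
    densitometry_au = round(runif(n, 10, 100), 2)
  )
  nec_cohort(piglets, vitals, feeds, biomarkers, necropsy)
}

## small simulated cohort (reduced group sizes, default dynamics), cached
.fixture_env <- new.env(parent = emptyenv())
small_cohort <- function() {
  if (is.null(.fixture_env$small)) {
    .fixture_env$small <- simulate_cohort(
      sim_config(seed = 424L, n_per_group = c(F_NEC = 3L, NF_NEC = 3L, NO_NEC = 4L))
    )
  }
  .fixture_env$small
}

## noiseless configuration: pure mean curves, no offsets, no dips
noiseless_config <- function(seed = 11L,
                             n_per_group = c(F_NEC = 1L, NF_NEC = 1L, NO_NEC = 1L)) {
  cfg <- sim_config(seed = seed, n_per_group = n_per_group)
  for (ch in names(cfg$vitals)) {
    cfg$vitals[[ch]]$noise_sd <- 0
    for (g in names(cfg$vitals[[ch]]$groups)) {
      cfg$vitals[[ch]]$groups[[g]]$baseline_sd <- 0
      cfg$vitals[[ch]]$groups[[g]]$feed_dip_amp_pct <- 0
    }
  }
  cfg$biomarkers$noise_sdlog <- 0
  cfg$biomarkers$saa$noise_sdlog <- 0
  cfg$necropsy$noise_sd <- 0
  class(cfg) <- "nec_sim_config"
  cfg
}
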