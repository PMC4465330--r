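library(data.table)

test_that("identical configurations produce byte-identical cohorts", {
  cfg <- sim_config(seed = 77L, n_per_group = c(F_NEC = 1L, NF_NEC = 2L, NO_NEC = 2L))
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(a, d1); write_cohort(b, d2)
  for (f in necnirs:::COHORT_FILES) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("noiseless streams reproduce the piecewise-linear mean curve", {
  cfg <- noiseless_config()
  co <- simulate_cohort(cfg)
  ep <- downsample_to_epochs(co$vitals)
  for (g in c("F_NEC", "NF_NEC", "NO_NEC")) {
    id <- co$piglets[group == g, piglet_id][1]
    knots <- cfg$vitals$STO2$groups[[g]]$knots
    e <- ep[piglet_id == id & channel == "STO2" & !is.na(mean_value)]
    ## each epoch mean equals the mean of the curve over its samples
    ## (values are CSV-quantized to 1e-4, hence the tolerance)
    expected <- vapply(e$epoch_start_h, function(s) {
      t <- s + (0:29) / 1800
      t <- t[t < if (is.na(co$piglets[piglet_id == id, death_h])) 96
             else co$piglets[piglet_id == id, death_h]]
      mean(approx(knots[, "t_h"], knots[, "level"], xout = t, rule = 2)$y)
    }, numeric(1))
    expect_equal(e$mean_value, expected, tolerance = 1e-4)
  }
})

test_that("noiseless first-hour StO2 baselines equal the configured Table-1 levels", {
  co <- simulate_cohort(noiseless_config())
  ep <- downsample_to_epochs(co$vitals[channel == "STO2"])
  base <- compute_baseline(ep)
  base <- co$piglets[, .(piglet_id, group)][base, on = "piglet_id"]
  expect_equal(base[group == "F_NEC", baseline], 64.9, tolerance = 1e-4)
  expect_equal(base[group == "NF_NEC", baseline], 74.2, tolerance = 1e-4)
  expect_equal(base[group == "NO_NEC", baseline], 79.5, tolerance = 1e-4)
})

test_that("censoring truncates every stream at death", {
  co <- small_cohort()
  dead <- co$piglets[!is.na(death_h)]
  expect_gt(nrow(dead), 0)
  for (i in seq_len(nrow(dead))) {
    id <- dead$piglet_id[i]; dh <- dead$death_h[i]
    expect_lt(max(co$vitals[piglet_id == id, t_h]), dh)
    if (nrow(co$feeds[piglet_id == id])) {
      expect_lt(max(co$feeds[piglet_id == id, t_h]), dh)
    }
    expect_lte(max(co$biomarkers[piglet_id == id, t_h]), dh)
  }
  ## survivors are recorded through to the study end
  surv <- co$piglets[is.na(death_h), piglet_id]
  expect_true(all(co$vitals[piglet_id %in% surv, max(t_h), by = piglet_id]$V1 >
                    96 - 1e-3))
})

test_that("event times honor the fulminant and non-fulminant windows", {
  co <- simulate_cohort(sim_config(seed = 3L))
  p <- co$piglets
  f <- p[group == "F_NEC"]
  expect_true(all(f$symptom_onset_h > 48 & f$symptom_onset_h <= 54))
  expect_true(all(f$death_h > 54 & f$death_h <= 66))
  nf <- p[group == "NF_NEC"]
  expect_true(all(nf$symptom_onset_h >= 66 & nf$symptom_onset_h <= 72))
  expect_true(all(is.na(nf$death_h) | nf$death_h >= nf$symptom_onset_h))
  expect_true(all(is.na(p[group == "NO_NEC", death_h])))
  expect_true(all(is.na(p[group == "NO_NEC", symptom_onset_h])))
})

test_that("AR(1) noise has the configured lag-1 autocorrelation", {
  cfg <- sim_config(seed = 1L)
  cfg$vitals$STO2$ar1_phi <- 0.9
  cfg$vitals$STO2$noise_sd <- 3
  cfg$vitals$STO2$groups$NO_NEC$feed_dip_amp_pct <- 0
  class(cfg) <- "nec_sim_config"
  p <- list(piglet_id = "P01", group = "NO_NEC", death_h = NA_real_)
  set.seed(123)
  s <- simulate_vitals_channel(p, "STO2", cfg$vitals$STO2, numeric(0), cfg)
  ## remove the deterministic mean curve, then check the moment identity
  knots <- cfg$vitals$STO2$groups$NO_NEC$knots
  resid <- s$value - approx(knots[, "t_h"], knots[, "level"],
                            xout = s$t_h, rule = 2)$y
  resid <- resid - mean(resid)
  n <- length(resid)   # ~1.7e5 samples
  rho1 <- sum(resid[-1] * resid[-n]) / sum(resid^2)
  expect_equal(rho1, 0.9, tolerance = 0.02)
  expect_equal(sd(resid), 3, tolerance = 0.1)
})

test_that("noiseless biomarker draws equal the kinetic curve", {
  cfg <- noiseless_config()
  co <- simulate_cohort(cfg)
  kin <- cfg$biomarkers$groups$F_NEC
  f_id <- co$piglets[group == "F_NEC", piglet_id][1]
  death <- co$piglets[piglet_id == f_id, death_h]
  draws <- co$biomarkers[piglet_id == f_id]
  ## pre-feed draw at 42 h sits exactly at baseline
  expect_equal(draws[t_h == 42, ifabp_ng_ml], kin$ifabp_baseline)
  ## the final pre-mortem draw equals the kinetic value times the decay
  t_last <- max(draws$t_h)
  expected <- min(kin$plateau_peak,
                  kin$ifabp_baseline +
                    kin$rise_rate * max(0, t_last - 48 - kin$rise_onset_h)) *
    (1 - kin$premortem_decay_fraction)
  expect_equal(draws[t_h == t_last, ifabp_ng_ml], expected, tolerance = 1e-4)
  ## draws are on the 6-h grid and stop at death
  expect_true(all(draws$t_h %% 6 == 0))
  expect_lte(t_last, death)
})

test_that("necropsy scores respect group ranges and noiseless coupling is monotone", {
  co <- simulate_cohort(noiseless_config(
    n_per_group = c(F_NEC = 3L, NF_NEC = 3L, NO_NEC = 3L)))
  nt <- co$piglets[, .(piglet_id, group)][co$necropsy, on = "piglet_id"]
  expect_true(all(nt[group == "NO_NEC", nec_score] <= 1L))
  expect_true(all(nt[group == "NF_NEC", nec_score] %in% 2:4))
  expect_true(all(nt[group == "F_NEC", nec_score] %in% 4:6))
  ## zero noise: densitometry is a strictly decreasing map of the score
  if (var(nt$nec_score) > 0) {
    expect_equal(densitometry_correlation(nt)$rho, -1)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_per_group = c(F_NEC = 0L, NF_NEC = 1L, NO_NEC = 1L)),
               class = "nec_config_error")
  expect_error(sim_config(nonsense = 1), class = "nec_config_error")
  cfg <- sim_config()
  cfg$vitals$STO2$ar1_phi <- 1.2
  expect_error(necnirs:::validate_sim_config(cfg), class = "nec_config_error")
  expect_error(simulate_validation_plateaus(0), class = "nec_config_error")
})
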