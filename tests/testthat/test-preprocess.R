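library(data.table)

test_that("epoch means follow the arithmetic-mean oracle", {
  ## constant stream: one full epoch of 70s
  e <- downsample_to_epochs(make_stream(rep(70, 30)))
  expect_equal(nrow(e), 1L)
  expect_equal(e$mean_value, 70)
  expect_equal(e$n_samples, 30L)

  ## alternating 60/80 averages to 70
  e <- downsample_to_epochs(make_stream(rep(c(60, 80), 15)))
  expect_equal(e$mean_value, 70)

  ## random values: epoch mean equals mean() of the contained samples
  set.seed(9)
  v <- round(runif(90, 50, 90), 4)
  e <- downsample_to_epochs(make_stream(v))
  expect_equal(e$mean_value, c(mean(v[1:30]), mean(v[31:60]), mean(v[61:90])))
})

test_that("epochs below 50% coverage are marked missing", {
  e <- downsample_to_epochs(make_stream(rep(70, 10)))
  expect_true(is.na(e$mean_value))
  expect_equal(e$n_samples, 10L)
  ## 15 of 30 samples is exactly at threshold: kept
  e <- downsample_to_epochs(make_stream(rep(70, 15)))
  expect_equal(e$mean_value, 70)
})

test_that("epoch means are invariant to sample order within the epoch", {
  set.seed(4)
  v <- round(runif(30, 60, 90), 4)
  s1 <- make_stream(v)
  s2 <- copy(s1)[, value := rev(value)]   # same times, reversed values
  expect_equal(downsample_to_epochs(s1)$mean_value,
               downsample_to_epochs(s2)$mean_value)
})

test_that("downsampling a constant stream conserves the constant", {
  s <- make_stream(rep(81.5, 1800 * 3))   # 3 h of constant signal
  e <- downsample_to_epochs(s)
  expect_true(all(e$mean_value == 81.5))
  expect_equal(nrow(e), 180L)
})

test_that("unsorted streams are rejected", {
  s <- make_stream(rep(70, 30))
  s <- s[c(2, 1, 3:30)]
  expect_error(downsample_to_epochs(s), class = "nec_ordering_error")
})

test_that("baselines are first-hour epoch means", {
  ## constant at the fulminant baseline scale
  e <- downsample_to_epochs(make_stream(rep(64.9, 1800 * 2)))
  b <- compute_baseline(e)
  expect_equal(b$baseline, 64.9)

  ## three epochs 70/72/74 average to 72
  v <- c(rep(70, 30), rep(72, 30), rep(74, 30))
  b <- compute_baseline(downsample_to_epochs(make_stream(v)))
  expect_equal(b$baseline, 72)

  ## all epochs in the window missing -> animal excluded, with a message
  sparse <- make_stream(rep(70, 10))   # single sub-coverage epoch
  e <- downsample_to_epochs(sparse)
  expect_message(b <- compute_baseline(e), "excluded")
  expect_equal(nrow(b), 0L)
})

test_that("group trajectories respect the strict death boundary", {
  ## two piglets, one dies exactly on a grid point
  p <- make_piglets(c("P01", "P02"), c("F_NEC", "NO_NEC"),
                    death_h = c(60, NA), symptom_onset_h = c(50, NA))
  v <- rbind(
    make_stream(rep(70, 1800 * 59.9), "P01"),
    make_stream(rep(80, 1800 * 62), "P02")
  )
  e <- downsample_to_epochs(v)
  tr <- group_trajectory(e, p, grid_step_h = 3, study_end_h = 60)
  ## at t = 57 the dying piglet still contributes
  expect_equal(tr[group == "F_NEC" & grid_h == 57, n_alive], 1L)
  ## at t = 60 it is excluded (death_h > t is strict)
  expect_equal(nrow(tr[group == "F_NEC" & grid_h == 60]), 0L)
  expect_equal(tr[group == "NO_NEC" & grid_h == 60, n_alive], 1L)
})

test_that("trajectory mean and sem follow the sd/sqrt(n) oracle", {
  p <- make_piglets(c("P01", "P02"), c("NO_NEC", "NO_NEC"))
  v <- rbind(make_stream(rep(60, 1800), "P01"),
             make_stream(rep(80, 1800), "P02"))
  tr <- group_trajectory(downsample_to_epochs(v), p, grid_step_h = 3,
                         study_end_h = 3)
  at0 <- tr[grid_h == 0]
  expect_equal(at0$mean, 70)
  expect_equal(at0$sem, sd(c(60, 80)) / sqrt(2))   # = 10
  expect_equal(at0$n_alive, 2L)
})

test_that("alive counts sum to the piglets alive at each grid time", {
  co <- small_cohort()
  e <- downsample_to_epochs(co$vitals[channel == "STO2"])
  tr <- group_trajectory(e, co$piglets)
  alive <- vapply(unique(tr$grid_h), function(t) {
    sum(is.na(co$piglets$death_h) | co$piglets$death_h > t)
  }, numeric(1))
  got <- tr[, .(n = sum(n_alive)), by = grid_h][order(grid_h), n]
  expect_equal(got, as.integer(alive))
})
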