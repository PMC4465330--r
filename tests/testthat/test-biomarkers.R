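library(data.table)

## rank-based Spearman oracle (mid-rank ties), independent of cor.test
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

test_that("densitometry correlation equals the rank oracle on small tables", {
  ## exact worked example: scores 0,2,4,6 against 10,8,6,4 -> rho = -1
  nt <- data.table(piglet_id = sprintf("P%02d", 1:4),
                   nec_score = c(0L, 2L, 4L, 6L),
                   densitometry_au = c(10, 8, 6, 4))
  expect_equal(densitometry_correlation(nt)$rho, -1)

  ## random small tables, with ties
  set.seed(13)
  for (rep in 1:10) {
    n <- sample(4:12, 1)
    nt <- data.table(piglet_id = sprintf("P%02d", 1:n),
                     nec_score = sample(0:6, n, replace = TRUE),
                     densitometry_au = round(runif(n, 0, 100), 1))
    if (var(nt$nec_score) == 0) next
    expect_equal(densitometry_correlation(nt)$rho,
                 spearman_oracle(nt$densitometry_au, nt$nec_score))
  }
})

test_that("rho is invariant under strictly monotone transforms and bounded", {
  set.seed(2)
  nt <- data.table(piglet_id = sprintf("P%02d", 1:10),
                   nec_score = sample(0:6, 10, replace = TRUE),
                   densitometry_au = round(runif(10, 1, 100), 1))
  rho <- densitometry_correlation(nt)$rho
  expect_gte(rho, -1); expect_lte(rho, 1)
  nt2 <- copy(nt)[, densitometry_au := log(densitometry_au)]
  expect_equal(densitometry_correlation(nt2)$rho, rho)
})

test_that("degenerate necropsy tables are refused", {
  nt <- data.table(piglet_id = c("P01", "P02"), nec_score = c(1L, 2L),
                   densitometry_au = c(5, 6))
  expect_error(densitometry_correlation(nt), class = "nec_validation_error")
  nt <- data.table(piglet_id = sprintf("P%02d", 1:5), nec_score = 3L,
                   densitometry_au = 1:5)
  expect_error(densitometry_correlation(nt),
               class = "nec_degenerate_correlation_error")
})

test_that("trajectory summaries compute pre-feed means and peak means", {
  p <- make_piglets(c("P01", "P02"), c("F_NEC", "NO_NEC"),
                    death_h = c(60, NA), symptom_onset_h = c(50, NA))
  b <- rbind(
    data.table(piglet_id = "P01", t_h = c(42, 48, 54, 60),
               ifabp_ng_ml = c(0.04, 0.04, 1.0, 2.0), saa_ng_ml = 1),
    data.table(piglet_id = "P02", t_h = c(42, 48, 54, 60),
               ifabp_ng_ml = c(0.08, 0.10, 0.09, 0.11), saa_ng_ml = 1)
  )
  ts <- trajectory_summary(b, p, "ifabp")
  exc <- ts$excursion
  expect_equal(exc[group == "F_NEC", pre_feed_mean], 0.04)
  expect_equal(exc[group == "F_NEC", post_feed_peak_mean], 2.0)
  expect_equal(exc[group == "NO_NEC", post_feed_peak_mean], 0.11)
  ## grid means carry sem and n
  expect_equal(ts$grid[group == "F_NEC" & t_h == 54, mean], 1.0)
  expect_equal(ts$grid[group == "F_NEC" & t_h == 54, n], 1L)
  ## all-zero draws collapse to zero pre and peak
  b0 <- copy(b)[, ifabp_ng_ml := 0]
  exc0 <- trajectory_summary(b0, p, "ifabp")$excursion
  expect_equal(exc0$pre_feed_mean, c(0, 0))
  expect_equal(exc0$post_feed_peak_mean, c(0, 0))
})

test_that("the peak statistic is order-invariant and a true maximum", {
  p <- make_piglets("P01", "NF_NEC")
  vals <- c(0.2, 1.4, 0.9, 0.5)
  b <- data.table(piglet_id = "P01", t_h = c(48, 54, 60, 66),
                  ifabp_ng_ml = vals, saa_ng_ml = 1)
  peak1 <- trajectory_summary(b, p, "ifabp")$excursion$post_feed_peak_mean
  b2 <- copy(b)[, ifabp_ng_ml := rev(vals)]
  peak2 <- trajectory_summary(b2, p, "ifabp")$excursion$post_feed_peak_mean
  expect_equal(peak1, max(vals))
  expect_equal(peak2, peak1)
})

test_that("pooled post-feed means split draws into NEC and No-NEC classes", {
  p <- make_piglets(c("P01", "P02"), c("NF_NEC", "NO_NEC"))
  b <- data.table(piglet_id = c("P01", "P01", "P02", "P02"),
                  t_h = c(42, 54, 42, 54),
                  ifabp_ng_ml = c(9, 0.8, 9, 0.1), saa_ng_ml = 1)
  pool <- pooled_group_mean(b, p, "ifabp")
  ## pre-feed draws (t < 48) are excluded
  expect_equal(pool$nec_mean, 0.8)
  expect_equal(pool$no_nec_mean, 0.1)
  expect_error(
    pooled_group_mean(b[piglet_id == "P01"], p[piglet_id == "P01"], "ifabp"),
    class = "nec_empty_class_error"
  )
})

test_that("simulated SAA kinetics are shared across groups", {
  cfg <- noiseless_config()
  co <- simulate_cohort(cfg)
  b <- co$piglets[, .(piglet_id, group)][co$biomarkers, on = "piglet_id"]
  ## at any common draw time, all groups have identical SAA values
  common <- b[, .N, by = t_h][N == 3, t_h]
  spread <- b[t_h %in% common, .(d = diff(range(saa_ng_ml))), by = t_h]
  expect_true(all(spread$d < 1e-9))
})
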