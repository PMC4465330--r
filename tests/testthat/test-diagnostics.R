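library(data.table)

## brute-force oracle: direct confusion-matrix counting at one threshold
oracle_point <- function(scores, labels, t, orientation) {
  called <- if (orientation == "lower") scores < t else scores > t
  c(sens = sum(called & labels) / sum(labels),
    spec = sum(!called & !labels) / sum(!labels))
}

test_that("ROC sens/spec equal the brute-force oracle at every threshold", {
  set.seed(31)
  for (rep in 1:8) {
    n <- sample(20:200, 1)
    orientation <- sample(c("lower", "higher"), 1)
    ## draws with ties to exercise the tie handling
    scores <- round(rnorm(n, 70, 8), sample(c(0, 1), 1))
    labels <- rbinom(n, 1, 0.4) == 1
    if (!any(labels) || all(labels)) next
    roc <- roc_curve(scores, labels, orientation)
    for (i in seq_along(roc$thresholds)) {
      o <- oracle_point(scores, labels, roc$thresholds[i], orientation)
      expect_equal(roc$sens[i], o[["sens"]])
      expect_equal(roc$spec[i], o[["spec"]])
    }
  }
})

test_that("AUC equals the normalized Mann-Whitney U statistic", {
  set.seed(17)
  for (rep in 1:10) {
    n <- sample(20:120, 1)
    scores <- round(rnorm(n, 0, 1), 1)
    labels <- rbinom(n, 1, 0.5) == 1
    if (!any(labels) || all(labels)) next
    for (orientation in c("lower", "higher")) {
      roc <- roc_curve(scores, labels, orientation)
      pos <- scores[labels]; neg <- scores[!labels]
      cmp <- outer(pos, neg, function(a, b) {
        if (orientation == "lower") (a < b) + 0.5 * (a == b)
        else (a > b) + 0.5 * (a == b)
      })
      expect_equal(roc$auc, mean(cmp))
    }
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(55)
  scores <- rnorm(150, 70, 8)
  labels <- rbinom(150, 1, 0.5) == 1
  roc <- roc_curve(scores, labels, "lower")
  ref <- pROC::roc(response = labels, predictor = scores,
                   direction = ">", quiet = TRUE)   # low score = positive
  expect_equal(roc$auc, as.numeric(pROC::auc(ref)))
})

test_that("perfect separation yields a separating Youden cutoff", {
  roc <- roc_curve(c(70, 72, 78, 80), c(TRUE, TRUE, FALSE, FALSE), "lower")
  expect_equal(roc$auc, 1)
  expect_equal(roc$sens_at_cutoff, 1)
  expect_equal(roc$spec_at_cutoff, 1)
  expect_gt(roc$chosen_cutoff, 72)
  expect_lte(roc$chosen_cutoff, 78)
})

test_that("degenerate inputs are handled as specified", {
  expect_error(roc_curve(1:5, rep(TRUE, 5)), class = "nec_degenerate_labels_error")
  ## all scores identical: chance-level AUC
  roc <- roc_curve(rep(3, 10), rep(c(TRUE, FALSE), 5), "higher")
  expect_equal(roc$auc, 0.5)
  ## boundary threshold: everything called negative
  cf <- confusion_at(c(70, 75, 80), c(TRUE, TRUE, FALSE), 69, "lower")
  expect_equal(cf$sens, 0)
  expect_equal(cf$spec, 1)
})

test_that("labels independent of scores give chance-level AUC on average", {
  set.seed(99)
  aucs <- replicate(200, {
    scores <- rnorm(40)
    roc_curve(scores, sample(rep(c(TRUE, FALSE), 20)), "higher")$auc
  })
  expect_equal(mean(aucs), 0.5, tolerance = 0.02)
})

test_that("Youden cutoff is equivariant under strictly monotone transforms", {
  set.seed(7)
  scores <- rnorm(60, 70, 6)
  labels <- scores + rnorm(60, 0, 6) < 70
  roc <- roc_curve(scores, labels, "lower")
  trans <- function(x) x^3 / 1000   # strictly increasing
  roc2 <- roc_curve(trans(scores), labels, "lower")
  expect_equal(roc2$chosen_cutoff, trans(roc$chosen_cutoff))
  expect_equal(roc2$auc, roc$auc)
  expect_equal(roc2$sens_at_cutoff, roc$sens_at_cutoff)
})

test_that("worked I-FABP example: cutoff 0.25 separates the draws", {
  cf <- confusion_at(c(0.04, 0.3, 1.9), c(FALSE, TRUE, TRUE), 0.25, "higher")
  expect_equal(cf$sens, 1)
  expect_equal(cf$spec, 1)
  ## No-NEC-only draws at 0.09 under the same forced threshold: spec 1
  cf <- confusion_at(c(0.09, 0.09, 0.3), c(FALSE, FALSE, TRUE), 0.25, "higher")
  expect_equal(cf$spec, 1)
})

test_that("screening wrappers label by eventual NEC status", {
  co <- small_cohort()
  e <- downsample_to_epochs(co$vitals)
  scr <- screen_sto2(e, co$piglets)
  n_epochs <- nrow(e[channel == "STO2" & !is.na(mean_value) &
                       epoch_start_h < 48])
  expect_equal(scr$n_scores, n_epochs)
  expect_equal(scr$roc$n_pos + scr$roc$n_neg, n_epochs)
  ## animal-level option collapses to one score per animal
  scr_a <- screen_sto2(e, co$piglets, unit = "animal")
  expect_equal(scr_a$n_scores, nrow(co$piglets))
  ## forced threshold is honored in the confusion summary
  scr_f <- screen_ifabp(co$biomarkers, co$piglets, threshold = 0.25)
  expect_equal(scr_f$confusion$threshold, 0.25)
  expect_error(screen_sto2(e, co$piglets, window_h = c(200, 300)),
               class = "nec_empty_input_error")
})
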