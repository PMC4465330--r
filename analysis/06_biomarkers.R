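#!/usr/bin/env Rscript
## Biomarker trajectories and the tissue correlation: I-FABP group curves
## (study: pooled post-feed 0.66 vs 0.09 ng/mL; fulminant excursion
## 0.04 -> 1.87 ng/mL), SAA as a non-discriminating control, and Spearman
## correlation of jejunal I-FABP densitometry with the histologic NEC score
## (study: rs = -0.79).

suppressMessages({library(necnirs); library(data.table); library(jsonlite)})

cohort <- simulate_cohort(sim_config(seed = 42L))
p <- cohort$piglets

ifabp <- trajectory_summary(cohort$biomarkers, p, "ifabp")
cat("I-FABP excursion by group (ng/mL):\n")
print(ifabp$excursion[, .(group, pre_feed_mean = round(pre_feed_mean, 3),
                          post_feed_peak_mean = round(post_feed_peak_mean, 2))])

pool <- pooled_group_mean(cohort$biomarkers, p, "ifabp")
cat(sprintf("\nPooled post-feed I-FABP: NEC %.2f vs No-NEC %.2f ng/mL\n",
            pool$nec_mean, pool$no_nec_mean))

saa <- trajectory_summary(cohort$biomarkers, p, "saa")
## compare SAA only over draws where every animal is still alive (t <= 54 h:
## the earliest fulminant death is after 54 h); SAA rises with time in all
## groups, so pooling censored late draws would separate groups spuriously
saa_cmp <- local({
  b <- p[, .(piglet_id, group)][cohort$biomarkers[t_h <= 54], on = "piglet_id"]
  gated_group_test(b$saa_ng_ml, b$group, piglet = b$piglet_id, time = b$t_h)
})
cat(sprintf("SAA group comparison over the common window: %s p = %.3g (no expected separation)\n",
            saa_cmp$method, saa_cmp$global_p))

rho <- densitometry_correlation(cohort$necropsy)
cat(sprintf("\nDensitometry vs NEC score: Spearman rho = %.2f (p = %.2g, n = %d)\n",
            rho$rho, rho$p_value, rho$n))

dir.create("results", showWarnings = FALSE)
fwrite(ifabp$grid, "results/ifabp_trajectory.csv")
fwrite(saa$grid, "results/saa_trajectory.csv")
write_json(list(rho = rho$rho, p_value = rho$p_value, n = rho$n),
           "results/densitometry_correlation.json", auto_unbox = TRUE, digits = NA)
cat("wrote results/ifabp_trajectory.csv, results/saa_trajectory.csv, results/densitometry_correlation.json\n")
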