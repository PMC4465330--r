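#!/usr/bin/env Rscript
## Screening-cutoff derivation. Abdominal StO2: epoch-level ROC over the
## pre-feed window (hours 0-48), low values call NEC (study boundary:
## StO2 < 75%). Plasma I-FABP: sample-level ROC over post-feed draws, high
## values call NEC (study boundary: > 0.25 ng/mL).

suppressMessages({library(necnirs); library(data.table)})

cohort <- simulate_cohort(sim_config(seed = 42L))
epochs <- downsample_to_epochs(cohort$vitals[channel == "STO2"])

scr_s <- screen_sto2(epochs, cohort$piglets)
cat("Abdominal StO2 screening (epoch level, hours 0-48):\n")
print(scr_s$roc)

scr_i <- screen_ifabp(cohort$biomarkers, cohort$piglets)
cat("\nPlasma I-FABP screening (sample level, post-feed draws):\n")
print(scr_i$roc)

## operating point at the study's printed boundaries, for comparison
at75 <- screen_sto2(epochs, cohort$piglets, threshold = 75)$confusion
at025 <- screen_ifabp(cohort$biomarkers, cohort$piglets, threshold = 0.25)$confusion
cat(sprintf("\nAt StO2 < 75%%: sens %.2f, spec %.2f\n", at75$sens, at75$spec))
cat(sprintf("At I-FABP > 0.25 ng/mL: sens %.2f, spec %.2f\n",
            at025$sens, at025$spec))

dir.create("results", showWarnings = FALSE)
fwrite(data.table(threshold = scr_s$roc$thresholds, sens = scr_s$roc$sens,
                  spec = scr_s$roc$spec), "results/roc_sto2.csv")
fwrite(data.table(threshold = scr_i$roc$thresholds, sens = scr_i$roc$sens,
                  spec = scr_i$roc$spec), "results/roc_ifabp.csv")
cat("wrote results/roc_sto2.csv, results/roc_ifabp.csv\n")
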