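# necnirs

Early detection of necrotizing enterocolitis (NEC) from continuous abdominal
near-infrared spectroscopy (NIRS) and intermittent plasma intestinal fatty
acid-binding protein (I-FABP), in a premature-piglet monitoring design.

NEC is the most common gastrointestinal emergency of premature neonates and
is usually recognized only after clinical signs appear. The cohort design
this package analyses monitors premature piglets from birth: heart rate,
pulse-oximetry SpO2 and abdominal tissue oxygen saturation (StO2, from an
abdominal NIRS probe) sampled every 2 seconds; 48 h of parenteral nutrition
followed by enteral feeds every 3 h until 96 h or death; plasma I-FABP and
serum amyloid A drawn every 6 h; and necropsy with ordinal histologic NEC
scoring. Animals split into fulminant NEC (f-NEC, dead within 18 h of the
first feed), non-fulminant NEC (nf-NEC) and No-NEC.

The package is aimed at researchers developing or evaluating
pre-symptomatic NEC screening: it provides both the analysis pipeline and a
tested synthetic cohort generator whose defaults encode the study design,
so every stage can be exercised and benchmarked without access to raw
recordings (none are publicly deposited).

## The statistics at its core

* **Epoching** — 2-s streams averaged into 1-minute epochs
  (half-open bins; epochs with < 50% coverage marked missing), with
  first-hour per-animal baselines and censoring-aware 3-hourly group
  trajectories (animals contribute at grid time *t* only while
  `death_h > t`).
* **Peri-prandial StO2 variability** — for each of the first two enteral
  feeds, 15-minute window means just before (`m_pre`) and after (`m_post`)
  the feed, scored as the unsigned percent change
  `|m_post − m_pre| / m_pre × 100`, averaged per animal and pooled NEC vs
  No-NEC (study contrast: 10.1% vs 6.3%).
* **NIRS calibration** — monitor StO2 regressed on the weighted
  arterio-venous composite reference `REF = 0.3·SaO2 + 0.7·ScvO2` over four
  FiO2 plateaus per validation piglet, with a meconium-stratum intercept
  (study fit: R² ≈ 0.77); the fitted line inverts to a correction
  `(raw − b)/a`.
* **Screening cutoffs** — empirical ROC curves with trapezoidal AUC and
  Youden-index cutoffs (`J = sens + spec − 1`; ties resolve toward
  sensitivity): epoch-level StO2 over pre-feed hours 0–48 with
  lower-is-positive orientation (study boundary StO2 < 75%), and
  sample-level post-feed I-FABP with higher-is-positive orientation (study
  boundary > 0.25 ng/mL).
* **Biomarker summaries** — group trajectories, pooled post-feed I-FABP
  means (0.66 vs 0.09 ng/mL), the fulminant pre-feed→peak excursion
  (0.04 → 1.87 ng/mL), and Spearman rank correlation of jejunal I-FABP
  densitometry with NEC score (rs ≈ −0.79).
* **Gated testing** — Shapiro-Wilk per group, then repeated-measures/one-way
  ANOVA with Tukey post-hoc, or Kruskal-Wallis, at α = 0.05.

## Worked example

```r
library(necnirs)

cohort <- simulate_cohort(sim_config(seed = 42))
report <- run_report(cohort)
```

The default cohort reproduces the study bookkeeping — 38 piglets, groups
7/14/17, NEC incidence 55% — and the report prints (seed 42):

```
  NEC incidence:        55%
  Pooled StO2 means:    f-NEC 69.0 / nf-NEC 70.2 / No-NEC 76.8 %
  Variability:          NEC 10.4% vs No-NEC 6.3%
  StO2 cutoff:          75.5% (sens 0.71, spec 0.73)
  I-FABP cutoff:        0.18 ng/mL (sens 0.46, spec 0.99)
  Pooled I-FABP:        NEC 0.72 vs No-NEC 0.09 ng/mL
  f-NEC I-FABP:         0.04 -> 2.07 ng/mL
  Densitometry rho:     -0.78
```

Reading the numbers: NEC animals run several StO2 points below healthy
animals for the whole study and react to feeds with deflections half again
as large; the Youden cutoff on pre-feed epochs lands at the study's 75%
boundary; plasma I-FABP stays at the assay floor until feeds begin and then
rises steeply in animals destined for NEC, while tissue I-FABP falls with
histologic severity (strongly negative rank correlation). Single-cohort
values scatter around the design values (e.g. the pooled nf-NEC mean of
70.2 here vs 71.9 in expectation) because each cohort draws 38 animals with
realistic between-animal spread; the replicate-averaged recoveries are much
tighter.

The numbered drivers under `analysis/` run the same pipeline stage by
stage (`01_simulate.R` … `07_report.R`), printing what each stage found and
writing its tables under `results/`.

## Package layout

```
R/                  cohort data model + CSV IO, simulator, epoching,
                    peri-prandial statistic, calibration, ROC diagnostics,
                    biomarker summaries, gated stats and report
analysis/           numbered narrative drivers over the package
scripts/acceptance.R  headline-quantity recomputation (JSON out)
vignettes/          methods vignette: models, assumptions, choices
tests/testthat/     unit, property and acceptance suites
```
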