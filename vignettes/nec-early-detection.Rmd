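---
title: "Early NEC detection from abdominal NIRS and plasma I-FABP: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Early NEC detection from abdominal NIRS and plasma I-FABP: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Necrotizing enterocolitis (NEC) in premature neonates is usually recognized
only after clinical signs appear, when the disease may already be fulminant.
The premature-piglet model this package reproduces monitors animals
continuously from birth — abdominal near-infrared spectroscopy (A-NIRS,
reporting splanchnic tissue oxygen saturation StO2), pulse-oximetry SpO2 and
heart rate every 2 seconds — through 48 h of parenteral nutrition and a
further 48 h of 3-hourly enteral feeds, with plasma drawn every 6 h for
intestinal fatty acid-binding protein (I-FABP) and serum amyloid A (SAA).
Animals are classified at necropsy as fulminant NEC (f-NEC: symptomatic
within 6 h of the first feed, dead by 18 h after feeds), non-fulminant NEC
(nf-NEC: signs 18–24 h after feeds, a minority surviving to 96 h) or No-NEC.

The analytical questions are: do pre-symptomatic StO2 levels and their
peri-prandial variability predict NEC; does post-feed plasma I-FABP confirm
it; and how well does the NIRS monitor track true splanchnic oxygenation?

`necnirs` implements the full pipeline — epoching, baselines,
censoring-aware trajectories, the peri-prandial statistic, screening ROC
cutoffs, biomarker summaries, the necropsy correlation, NIRS calibration and
a gated statistical report — driven by a synthetic cohort generator, because
no raw recordings from the original cohort are publicly deposited.

## The synthetic cohort generator

The generator (`sim_config()`, `simulate_cohort()`) is first-class, tested
code whose defaults encode the study conditions rather than free knobs:

* **Design**: 38 animals (7 f-NEC / 14 nf-NEC / 17 No-NEC) from 4 litters;
  2-s sampling to 96 h or death; feeds at 48, 51, …, 93 h; draws at 0, 6,
  …, 96 h.
* **Vitals model**: per channel and group, a piecewise-linear mean curve
  over [0, 96] h, plus a per-animal baseline offset drawn from the
  between-animal SDs of the baseline table (e.g. StO2 6.7 / 6.8 / 7.6
  percentage points), plus stationary AR(1) noise on the 2-s grid
  (marginal SD 3 points for StO2, lag-1 autocorrelation 0.95, a correlation
  time of ~80 s chosen to mimic slow physiological drift rather than
  instrument white noise). Values are clamped to channel bounds.
* **Knot curves**: the StO2 curves start at the group baselines (64.9 /
  74.2 / 79.5 %), and their censoring-weighted time averages reproduce the
  whole-study pooled means (69 / 71.9 / 78.4 %); the nf-NEC curve troughs
  at 67 % about 24 h after feeds begin. SpO2 and HR curves follow the
  described recovery/decline shapes; their exact forms are configuration,
  not contract.
* **Feeding response**: each feed subtracts a transient dip
  `amp/100 × pre-feed level × exp(−Δt/τ)` from StO2 with τ = 7.5 min, so
  the deflection has largely recovered within the 15-minute post-feed
  window. Amplitudes (23.3 % of the pre-feed level for NEC animals, 14.65 %
  for No-NEC) are the free parameters calibrated so the peri-prandial
  statistic averages 10.1 % vs 6.3 % — the study's reported group contrast.
* **Censoring**: f-NEC symptom onset uniform in (49, 54] h with death
  uniform in (54, 66] h; nf-NEC onset uniform in [66, 72] h, survival to
  96 h with probability 5/14, otherwise death 6–18 h after onset. Vitals
  and feeds stop strictly before death; the biomarker schedule allows a
  final draw at death.
* **I-FABP kinetics**: flat group baseline (0.04 / 0.01 / 0.09 ng/mL),
  then a linear rise starting 2 h (f-NEC) or 18 h (nf-NEC) after the first
  feed at 0.42 / 0.095 ng/mL/h toward plateaus of 2.65 / 3.03 ng/mL; the
  final pre-mortem draw of a dying animal is attenuated by 20 % (the
  exhaustion/venous-congestion effect seen in the sickest animals).
  Multiplicative mean-one lognormal assay noise (sdlog 0.4) keeps values
  positive and right-skewed. SAA rises identically in all groups
  (no discriminating signal, by design).
* **Necropsy**: ordinal NEC scores drawn per group (No-NEC ∈ {0,1},
  nf-NEC ∈ {2..4}, f-NEC ∈ {4..6}); densitometry is `100 − 14·score`
  arbitrary units plus Gaussian noise (SD 21), floored at zero — a linear
  inverse coupling whose Spearman correlation over a default cohort
  averages ≈ −0.79.
* **Validation sub-study**: five instrumented piglets at FiO2 plateaus
  0.08 / 0.21 / 0.60 / 1.0, SaO2 drawn per plateau (order-enforced in
  FiO2), ScvO2 an arteriovenous gap (12 ± 5 points, floored at 2) below
  it, and the monitor reading equal to the composite reference plus
  Gaussian noise with SD 12 points — the level at which the calibration
  regression's R² averages ≈ 0.77.

Where the study prints a quantity, the corresponding default is the printed
value; free parameters with no printed counterpart (epoch-level noise, AR
memory, dip recovery time, plateau saturations) were fixed once at
physiologically plausible values — or, where a printed group-level result
constrains them indirectly (the feed-dip amplitudes, the plateau noise, the
densitometry noise), calibrated against that result using replicate
simulations — and then frozen. They are not adjusted per analysis.

### What the generator does *not* emulate

No mechanistic physiology (cardiac output, vascular resistance, oxygen
transport), no raw optical signals, no motion or probe-contact artifacts,
no diurnal structure, no correlation between a piglet's vitals offset and
its biomarker kinetics beyond group membership, and no litter effects.
Passing the recovery tests therefore shows that the *analysis pipeline* is
correct and unbiased under the study's statistical structure — not that the
pipeline would be robust to every artifact of real monitor data.

## Analysis conventions and numerical choices

* **Epochs** are half-open 1-minute bins aligned to the birth clock; an
  epoch needs at least 15 of its nominal 30 samples, otherwise it is kept
  as missing and never interpolated. Emitted times are quantized to 1e-7 h
  and values to 1e-4 so the CSV round trip is bit-exact; epoch binning
  allows a 1e-4-minute slack so quantized boundary samples land in the
  correct bin.
* **Baseline** is the mean of non-missing epochs in the first hour of
  recording (the probe is placed within 2 h of birth; the study does not
  define "baseline" numerically, so the window is a documented choice).
* **Group trajectories** average animals with `death_h > t` at each 3-h
  grid point (strict inequality: an animal dying on a grid point is
  excluded there), over a centered ±1.5 h epoch window; dead animals are
  never carried forward, and the SEM is omitted below two animals.
* **Peri-prandial statistic**: pre-window `[feed − 15 min, feed)`,
  post-window `[feed, feed + 15 min)`, each needing ≥ 8 usable epochs; the
  percent change is unsigned (variability is a magnitude concept and both
  groups are reported as positive percentages) and taken relative to the
  pre-feed window mean, not the birth baseline, which is hours stale by
  the first feed. A signed variant exists behind `signed = TRUE`. Only
  feeds 1–2 (48 and 51 h) enter; all f-NEC animals are still alive then.
* **ROC unit of analysis**: the study reports 97 %/97 % for the StO2 < 75 %
  boundary without stating the observation unit; at animal level 97 %
  sensitivity is unattainable with 21 NEC animals (20/21 = 95.2 %). StO2
  screening is therefore epoch-level over hours 0–48 (pre-symptomatic,
  pre-feed) and I-FABP screening sample-level over post-feed draws, with
  animal-level alternatives behind `unit = "animal"`. Cutoff *location*
  (≈ 75 % and ≈ 0.25 ng/mL) is the recovery target, not the printed
  sensitivity/specificity pair.
* **Youden ties** resolve toward higher sensitivity (screening context),
  then toward the smaller-magnitude threshold. AUC is trapezoidal and
  equals the tie-corrected Mann-Whitney statistic.
* **Calibration** regresses the monitor reading on the composite reference
  `0.3·SaO2 + 0.7·ScvO2`; meconium, an absorbing chromophore, enters as a
  stratum-specific intercept under a shared slope (the study gives no
  functional form for the interference). The reported Pearson r is
  `cor(measured, fitted)`, so r² equals the model R² in both the one- and
  two-stratum layouts. Calibration is off by default in the cohort
  analysis, which uses raw monitor readings as the study does.
* **Gated testing**: Shapiro-Wilk per group at α = 0.05 on analysis-unit
  values (per-animal statistics, never raw 2-s samples); all groups normal
  → ANOVA (repeated-measures with an animal error stratum when a time
  structure is present, one-way otherwise) with Tukey HSD post-hoc on the
  per-animal values (the study names no post-hoc method; Tukey-style
  family-wise control is the conventional choice); any group non-normal →
  Kruskal-Wallis with Holm-adjusted pairwise Wilcoxon. Post-hoc p-values
  are attached only when the global test is significant with ≥ 3 groups.
* **Biomarker pooling**: the NEC vs No-NEC contrast (0.66 vs 0.09 ng/mL)
  pools all post-feed draws across animals (draw-level pooling; per-animal
  pooling is available behind `unit = "animal"`). Pre-feed draws are
  excluded — pre-feed levels sit at the assay floor. The pre-mortem
  I-FABP decline is represented in the generator but feeds no statistic;
  it is descriptive only.

## Problem sizes and replication

A default cohort is ~17.5 million vitals samples; simulating and fully
analysing one takes roughly half a minute on a single core. Parameter
recovery uses 20 replicate cohorts (distinct seeds) and compares the
replicate mean against the study value within twice the Monte-Carlo
standard error; the calibration R² uses 50 replicate plateau sets; the
type-I-error property uses 2000 null replicates of the gated test at the
study's group sizes. These sizes keep every recovery estimate's Monte-Carlo
uncertainty well inside the comparison bands.

## Known limitations

* The piecewise-linear mean curves reproduce printed summaries, not the
  unpublished raw trajectories; shapes between knots are interpolations.
* The study's prose and printed table disagree in places (e.g. the No-NEC
  heart-rate spread and the internal consistency of the No-NEC HR range vs
  its whole-study mean); where they conflict, the printed table and the
  whole-study means were preferred.
* Epoch-level ROC treats epochs as exchangeable scores although they are
  strongly autocorrelated within animal; this matches the screening framing
  but inflates the effective sample size of the ROC — another reason cutoff
  location, not sensitivity/specificity, is the recovery target.
* The repeated-measures ANOVA uses a single animal error stratum and
  assumes sphericity; no correction (Greenhouse-Geisser or mixed model) is
  applied, matching the era of the original analysis.
* Sample-level I-FABP pooling includes the non-fulminant animals' pre-rise
  post-feed draws (near 0.01 ng/mL, below the No-NEC assay floor of
  0.09 ng/mL), so the whole-curve AUC can fall below 0.5 even though the
  upper tail separates cleanly; the Youden threshold still lands at the top
  of the No-NEC noise cloud (≈ 0.25 ng/mL) with high specificity.
* Because SAA rises with time in every group while NEC animals die early,
  naive pooling of per-animal SAA means separates groups through censoring
  alone; SAA comparisons are therefore restricted to draws in the window
  where all animals are alive (≤ 54 h), where no group signal exists by
  construction.

## Reproducing the analysis

```{r}
library(necnirs)

cohort <- simulate_cohort(sim_config(seed = 42))
report <- run_report(cohort, out_dir = "results/report")
str(report$metrics)
```

The numbered drivers under `analysis/` walk the same pipeline stage by
stage, and `scripts/acceptance.R` recomputes the replicate-averaged
headline quantities from scratch.
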