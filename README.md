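# pulsefuse

Joint analysis of synchronously acquired wrist pressure-pulse-wave (PPW)
and limb-lead ECG recordings for multi-class identification of coronary
heart disease (CHD) and its comorbidities. The package is aimed at
physiological-signal and biostatistics researchers who want a fully
reproducible, testable implementation of a fused pulse + ECG pipeline:

1. **Synthetic cohort generation** — two-channel records (60 s at
   1,100 Hz) for four study groups (healthy, CHD, CHD + hypertension,
   CHD + hypertension + diabetes), built from parametric beat models with
   exact ground-truth fiducials, beat-to-beat period variability,
   respiratory drift, 50 Hz powerline and 20–40 Hz EMG-band noise, and
   demographics drawn from the published group moments.
2. **Preprocessing** — 3rd-order 8 Hz Butterworth low-pass and natural
   cubic-spline baseline removal (through the pulse troughs) for the PPW
   channel; 0.2–0.5 Hz baseline extraction and two-stage 40 Hz / 20 Hz
   low-pass filtering for the ECG channel, all zero-phase.
3. **Fiducial delineation and features** — pulse landmarks
   (percussion peak H1, pre-tidal shoulder H2, tidal peak H3, dicrotic
   notch H4, dicrotic peak H5) and the time-domain feature vector
   (amplitudes, durations T, T1–T5, widths W1/W2, systolic/diastolic
   areas As/Ad, their ratios, and pulse-rate variability P-SDNN /
   P-rMSSD); P-QRS-T delineation on the ECG with segment/interval
   durations and heart-rate variability (SDNN, RMSSD, mean RR).
4. **Statistics** — group comparison via a Shapiro–Wilk screen routing to
   one-way ANOVA or Kruskal–Wallis (chi-square for categorical features),
   and a-priori chi-square power analysis by noncentral-distribution
   inversion.
5. **Class balancing and benchmarking** — from-scratch SMOTE (k nearest
   neighbors, synthesis only inside training folds by default), and
   grid-searched random forest / bagged trees / RBF-SVM benchmarking under
   stratified 5-fold cross-validation, including an importance-ranked
   sequential-forward-selection random forest (FS-RF), one-vs-rest ROC
   AUC, macro precision/recall/F1, and paired CV t-tests.

## The core quantities

For a pulse cycle of length `T` with onset-referenced amplitudes `H1..H5`
at times `T1..T5`, the feature vector includes the ratios `H2/H1, H3/H1,
H4/H1, H5/H1`, the relative timings `T1/T, T4/T, T1/T4, T5/T4`, the widths
`W1` (time above 2/3·H1) and `W2` (time above 4/5·H1), and the areas `As`
(onset→notch) and `Ad` (notch→cycle end). Rate variability uses the
standard definitions

    SDNN  = sd(RR_i)            RMSSD = sqrt(mean(diff(RR_i)^2))

on the pulse-period and RR series (ms). Classifier performance is scored
from the pooled out-of-fold confusion matrix via `Accuracy = (TP+TN)/N`,
`Precision = TP/(TP+FP)`, `Recall = TP/(TP+FN)` and
`F1 = 2·P·R/(P+R)` per class, with macro metrics as arithmetic means.

## Worked example

```r
library(pulsefuse)
library(dplyr)

# a small four-group cohort with the clinical noise profile
cohort <- synth_cohort(c(12, 12, 12, 12), seed = 1, duration = 20,
                       noise = noise_profile("clinical"))
features <- extract_features(cohort)

features |>
  group_by(group) |>
  summarise(T = median(T), QRS = median(QRS_seg), HR = mean(HR))
#> # A tibble: 4 × 4
#>   group     T    QRS    HR
#>   <fct> <dbl>  <dbl> <dbl>
#> 1 1     0.742 0.0709  77.9
#> 2 2     0.850 0.0773  69.6
#> 3 3     0.877 0.0764  67.0
#> 4 4     0.865 0.0739  71.5
```

The per-group medians land on the generator's calibrated targets: healthy
subjects (group 1) have the shortest pulse period and the narrowest QRS,
the comorbidity groups show the prolonged periods and conduction times the
cohort statistics are built to detect. A quick benchmark on the extracted
features:

```r
cv <- train_eval_cv(features, "group", algo = "rf",
                    grid = data.frame(ntree = 100, min_leaf = 1), seed = 1)
glance(cv)
#> # A tibble: 1 × 9
#>   algo  accuracy macro_precision macro_recall macro_f1 folds fold_acc_mean
#>   <chr>    <dbl>           <dbl>        <dbl>    <dbl> <int>         <dbl>
#> 1 rf        95.8            95.8         95.8     95.8     5          95.8
#> # ℹ 2 more variables: fold_acc_sd <dbl>, n <int>
```

an out-of-fold accuracy of 95.8% on 48 subjects — far above the 25%
four-class chance floor, driven by the calibrated group differences in
pulse morphology, conduction intervals and demographics. (Synthetic
cohorts are more separable than the real population the feature tables
describe: the generator reproduces group medians and variability, not the
clinical heterogeneity and feature overlap that limit real accuracy to
~75%.) `autoplot(cv)`
draws the pooled confusion matrix; `autoplot(record)` shows a signal
window with its ground-truth fiducials.

A full end-to-end run (synthesis → features → statistics → benchmark →
report files + manifest):

```r
cfg <- pipeline_config(seed = 1, counts = c(20, 20, 20, 20),
                       duration = 20, algos = c("rf", "fsrf"))
run <- run_pipeline(cfg, "runs/demo")
```

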