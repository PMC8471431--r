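# vwmflow

Non-invasive surveillance of arteriovenous fistula (AVF) access flow for
hemodialysis patients, from radar-sensed **vascular wall motion** (VWM).

A patent fistula is the lifeline of a dialysis patient; falling access flow
(stenosis on its way to thrombosis) is the main cause of access loss.
`vwmflow` implements, end to end, a screening pipeline in which a pulse
radar held over the fistula senses the periodic displacement of the vessel
wall, and a classifier flags records whose harmonic content betrays
turbulent, low-flow hemodynamics:

1. **Radar sensing model** — a damped sinusoidal pulse at carrier
   `f_p` is emitted, its echo from the wall at distance `R_o − Δr(t)` is
   mixed with a delayed reference and low-pass filtered, leaving the
   baseband `B(t) = B·sin(4π(R_o − Δr(t))/λ_p)`. Because the wall moves by
   only `Δr ≈ 0.028 mm ≪ R_o < 6 mm`, the baseband is affine in
   displacement: `B(t) = C1 − C2·Δr(t)`. Both closed forms and a
   pulse-level brute-force simulation of the mixing chain are provided, and
   tested against each other.
2. **Synthetic cohort generator** — quasi-periodic wall-displacement
   waveforms (harmonic series at the cardiac fundamental `f0`) for normal
   flow; for dysfunctional flow, a turbulence oscillation at 3–5× `f0`
   superimposed with a depth that falls logistically with access flow.
   Labels are access flows in mL/min.
3. **Acquisition chain** — Hamming-window linear-phase FIR band-pass
   (0.2–10 Hz) at the 64 Hz device rate, with group-delay compensation.
4. **Harmonic-ratio features** — one-sided FFT amplitude spectrum, cardiac
   fundamental detection, harmonic peaks `P1…P6`, and the five **harmonic
   ratios** `P2/P1, P3/P2, P4/P3, P5/P4, P6/P5` used as features.
5. **Feature screening** — pooled-variance two-sample t-tests of each
   ratio between low- and high-flow strata, from raw samples or directly
   from printed `(mean, SD, n)` summaries.
6. **Classification** — RBF-kernel SVM, stratified 10-fold
   cross-validation, confusion-matrix metrics (sensitivity, specificity,
   accuracy, PPV), decision-value export and ROC/AUC, swept over detection
   cutoffs 500/600/650/750 mL/min (positive class: flow ≤ cutoff).

## Worked example

```r
library(vwmflow)

cohort <- simulate_cohort(cohort_spec(n_patients = 45, seed = 7))
feats  <- feature_table(cohort)          # band-pass -> FFT -> P1..P6 -> HRs
head(feats[, c("patient_id", "flow_mL_min", "f0_hz", "hr32", "hr54")], 4)
#>   patient_id flow_mL_min f0_hz  hr32  hr54
#> 1       P001        1073  1.17 0.339 0.793
#> 2       P002        1236  1.17 0.584 0.704
#> 3       P003         664  1.41 0.752 0.862
#> 4       P004         486  1.47 0.743 3.655

screen_features(feats, cutoff = 600)[, c(1, 2, 5, 8, 10, 11)]
#>   harmonic_ratio mean_low mean_high difference  p_value significant
#> 1           hr21    0.353     0.364    -0.0113 0.667870       FALSE
#> 2           hr32    0.628     0.534     0.0934 0.195908       FALSE
#> 3           hr43    1.711     0.831     0.8800 0.000145        TRUE
#> 4           hr54    1.828     0.699     1.1296 0.000850        TRUE
#> 5           hr65    0.446     0.730    -0.2841 0.000279        TRUE

labelled <- label_cohort(feats, cutoff = 600)   # 11 dysfunction, 34 normal
cv <- cross_validate(labelled, k = 10, seed = 7)
confusion_metrics(cv$confusion)
#> $sensitivity_pct 100 ... $specificity_pct 100 ... $accuracy_pct 100
roc_analysis(cv$label, cv$decision_values)$auc
#> [1] 1
```

Patient P004 (486 mL/min) shows the signature of flow dysfunction: a
grossly elevated P5/P4 (`hr54` = 3.66) from the turbulence oscillation at
5× the cardiac fundamental. The screening table picks up the affected
ratios (elevated `hr43`/`hr54`, depressed `hr65` in the low-flow stratum),
and the cross-validated SVM separates this cohort perfectly; across seeds
the accuracy is typically in the 90s with specificity at 100%.

A thin command-line wrapper is installed at
`inst/scripts/vwm_pipeline.R` (subcommands `simulate`, `features`,
`evaluate`).

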