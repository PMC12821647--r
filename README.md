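# gazeload

Eye-gaze and self-report metrics for cognitive-load evaluation in simulated
driving.

## What it does

Driver cognitive load (CL) rises with road-environment complexity
(extraneous load: urban traffic vs. an empty highway) and with secondary
tasks (intrinsic load: an auditory N-Back performed while driving).
`gazeload` implements the full analysis pipeline for asking how well
oculomotor metrics and NASA-TLX self reports discriminate four driving
stages that cross those two axes — `HighwayDriving`, `HighwayNback`,
`UrbanDriving`, `UrbanNback`:

1. **Gaze geometry** — every 60 Hz frame's gaze ray is intersected with a
   *mobile reference plane* placed 112 cm along the head direction, by an
   exact linear solve of the plane equation
   `A(x−x₀) + B(y−y₀) + C(z−z₀) = 0` plus two line constraints; parallel
   and in-plane rays are flagged invalid.
2. **Oculomotor events** — fixations (inter-sample change < 1° for ≥ 6
   frames, capped at 1200), saccades (≥ 1°, 2–12 frames, amplitude ≤ 60°,
   amplitude-to-peak-velocity ratio ≤ 10, velocity floor), and blinks
   (eyelid derivative thresholds, 5–180 frames).
3. **Windowed metrics** — fixation duration, saccade velocity, blink
   number, stationary gaze entropy `SGE = −Σ pᵢ log₂ pᵢ` and gaze
   transition entropy `GTE = −Σ pᵢ Σ p(j|i) log₂ p(j|i)` over 30 × 30-px
   bins, on 30 s windows stepped by 1 s; windows need > 50% valid frames,
   participants at most 35% low-quality windows.
4. **NASA-TLX** — six scales on −4..+4 with the performance scale negated
   in the averaged answer.
5. **Discrimination & coherence** — per-subject expected-direction accuracy
   for each measure and stage pair; Spearman correlations by stage; Lin's
   concordance coefficient `ρc = 2s_xy / (s_x² + s_y² + (x̄−ȳ)²)` between
   rank-coded stages, gaze metrics and TLX scales, aggregating significant
   |ρc| as mean/min/max.

Because study datasets of this kind are not public, the package includes a
seeded synthetic-cohort generator (`simulate_cohort()`) with ground-truth
fixation/saccade/blink labels, used by the test suite to demonstrate event
recovery and ordinal-pattern discrimination end to end.

## Worked example

```r
library(gazeload)

cohort <- simulate_cohort(8, seed = 42, duration_s = 120)
report <- run_study(cohort = cohort, config = run_config(seed = 42))

report$stage_summary
#>            stage fixation_duration saccade_velocity blink_number  sge   gte n
#> 1 HighwayDriving               290              197        11.17 4.18 1.741 8
#> 2   HighwayNback               317               96        13.42 3.88 1.034 8
#> 3   UrbanDriving               250              148         6.39 5.30 0.763 8
#> 4     UrbanNback               281              135         9.18 4.79 1.214 8
```

The stage summary shows the ordinal structure the cohort encodes: fixations
are longest on the highway and lengthen further under the N-Back task, gaze
is most dispersed in urban driving (SGE 5.30 vs 4.18 bits), and scan paths
are least predictable on the plain highway (GTE 1.74 bits). The accuracy
table then reports, per measure and stage pair, the fraction of subjects
whose within-subject difference goes in the direction predicted by the CL
model (ties count 0):

```r
tidyr::pivot_wider(report$accuracy$gaze[, c("measure", "pair", "accuracy")],
                   names_from = "pair", values_from = "accuracy")
#>             measure HighwayDriving_vs_HighwayNback UrbanDriving_vs_UrbanNback
#> 1 fixation_duration                              1                      1.000
#> 2  saccade_velocity                              1                      0.875
#> 3      blink_number                              1                      0.875
#> 4               sge                              1                      1.000
#> 5               gte                              1                      1.000
#> 6           Average                              1                      0.950
#>   HighwayDriving_vs_UrbanDriving
#> 1                          1.000
#> 2                          0.875
#> 3                          1.000
#> 4                          1.000
#> 5                          1.000
#> 6                          0.975
```

An accuracy of 0.875 on eight subjects means seven of eight showed the
expected direction. `report$coherence` aggregates the absolute Lin
coefficients of significant components per pairing — in this cohort the
gaze metrics cohere most strongly with the highway-vs-urban stage contrast
(mean |ρc| 0.86), while TLX coherence is highest for the highway N-Back
contrast.

Every threshold above (plane distance, quality cut-offs, event gates,
window sizes, QC caps, the expected-direction table) is configuration with
the documented defaults — see `?run_config` and the methods vignette
(`vignettes/gazeload-methods.Rmd`).

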