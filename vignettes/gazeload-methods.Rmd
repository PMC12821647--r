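---
title: "Methods: windowed gaze metrics and load discrimination in gazeload"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed gaze metrics and load discrimination in gazeload}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

# The problem

Driver cognitive load (CL) can be manipulated along two axes: the complexity
of the road environment (urban traffic versus an empty highway — extraneous
load) and the presence of a secondary working-memory task such as an auditory
N-Back (intrinsic load). `gazeload` implements an analysis pipeline that asks
how well two families of measures — oculomotor metrics from a 60 Hz remote
eye tracker, and NASA-TLX self reports — discriminate four five-minute
driving stages (`HighwayDriving`, `HighwayNback`, `UrbanDriving`,
`UrbanNback`) that cross those two axes.

The pipeline has five computational layers, each exposed as plain functions:

1. **Geometry** — project each frame's gaze ray onto a mobile reference
   plane anchored to the head.
2. **Events** — segment the projected trajectory and the eyelid signal into
   fixations, saccades and blinks with fixed thresholds.
3. **Windowed metrics** — five gaze metrics on overlapping 30 s windows,
   with window- and participant-level quality control, averaged to stage
   means.
4. **Self report** — the adjusted NASA-TLX with performance inversion.
5. **Comparison statistics** — expected-direction discriminative accuracy,
   Spearman correlations, and Lin's concordance ("coherence") against
   rank-coded stages.

Because datasets of this kind are typically not public, the package ships a
seeded synthetic-cohort generator with ground-truth event labels. The
generator is first-class, tested code: every validation claim in the test
suite is a computation on its output.

# Gaze geometry

For each frame a plane is placed at distance $d$ (default **112 cm**, the
approximate screen distance of a fixed-base simulator) along the head
direction $\mathbf{n}$, through the point $\mathbf{p}_0 = \mathbf{h} + d\,
\mathbf{n}$, with $\mathbf{n}$ as its normal. The gaze ray
$\mathbf{o} + t\,\mathbf{g}$ is intersected with the plane by solving a
3×3 linear system: the plane equation
$A(x - x_0) + B(y - y_0) + C(z - z_0) = 0$ plus two line-membership
constraints taken from $\mathbf{g} \times (\mathbf{p} - \mathbf{o}) =
\mathbf{0}$. The two cross-product rows are chosen to omit the dominant
component of $\mathbf{g}$, which keeps the system full rank whenever the ray
is not parallel to the plane; parallel and in-plane rays
($|\mathbf{n} \cdot \mathbf{g}| < 10^{-9}$) are reported as
*no intersection* and the frame becomes invalid. Intersections behind the
gaze origin ($t \le 0$) are likewise treated as tracking noise. The unit
tests check this solver against an independent parametric oracle
$t = (D - \mathbf{n}\cdot\mathbf{o}) / (\mathbf{n}\cdot\mathbf{g})$ at
$10^{-8}$ cm.

The 2-D chart on the plane is deterministic: $\mathbf{u} =
\widehat{\mathbf{n} \times \mathrm{up}}$ with world-up $(0,1,0)$ (falling
back to $(1,0,0)$ for a vertical normal) and $\mathbf{v} = \mathbf{n} \times
\mathbf{u}$. Because the chart references world-up, projection is exactly
invariant under joint rigid rotations *about the vertical axis* — the
physically relevant family for a driver turning their head — but not under
arbitrary tilts; the tests assert the former. Plane coordinates are
continuous (cm) and scaled to pixels by `px_per_cm` (default **32**, a
typical monitor density, making one 30-px entropy bin ≈ 0.94 cm at the
plane); no rounding occurs before binning.

Frames are dropped when the tracker's head or gaze quality falls below
`quality_threshold` (default **1.0**: only optimal-quality frames are kept)
or the validity flag is off; dropped indices are retained for window-quality
accounting.

# Oculomotor events

At 60 Hz, with $\Delta_i$ the angular change between successive gaze
directions:

* **Fixations** are maximal runs with $\Delta_i < 1^\circ$ lasting at least
  **6 frames** (≥ 100 ms). Runs longer than **1200 frames** (20 s) are
  truncated at the cap and a new fixation begins, which preserves total
  fixation time under the cap.
* **Saccades** are maximal runs with $\Delta_i \ge 1^\circ$ lasting **2–12
  steps** (≈ 30–200 ms), with total amplitude ≤ **60°**,
  amplitude-to-peak-velocity ratio (AVR) ≤ **10**, and peak velocity at
  least **0.5°/frame** (30°/s) — the velocity floor is configurable because
  only the existence of the filter, not its value, is standard. AVR is
  computed as amplitude (deg) over peak velocity (deg/frame), the only
  reading under which plausible 2–12-frame events pass a gate of 10.
* **Blinks** are eyelid-signal closures bounded by a discrete derivative
  falling below $-d_{thr}$ and later rising above $+d_{thr}$, lasting
  **5–180 frames** (≈ 83–3000 ms). $d_{thr}$ defaults to a quarter of the
  signal's interquartile range — a scale-free rule that presumes a smooth,
  band-limited baseline (white measurement noise would require an absolute
  threshold instead).

Invalid frames break fixation/saccade runs; nothing is interpolated. Frames
inside detected blinks are masked before fixation/saccade segmentation by
default (`exclude_blink_frames`), so a blink splits the surrounding
fixation. Short stable runs that qualify as neither fixation nor saccade are
left unlabelled: the event definitions are not exhaustive and forcing a
partition would invent events. Saccade frame spans surrender their boundary
frames to adjacent fixations, so the two classes never overlap.

# Windowed metrics and quality control

Metrics are computed on **30 s windows advanced in 1 s steps** (271 windows
per 300 s stage). A window is usable only when *strictly* more than 50% of
its 1800 frames are valid. Events belong to the windows containing their
temporal midpoint (half-open on the right), so each event contributes once
per window. Per window: mean fixation duration (ms), mean saccade velocity
(reported in deg/s; an angular quantity is the natural detector-side unit,
and the report unit is configuration), blink count, and the two entropies:

* **SGE** $= -\sum_i p_i \log_2 p_i$, the Shannon entropy of fixation
  counts over 30 × 30-px grid cells anchored at the plane origin (half-open
  cells, floor semantics on negatives, no per-window re-centering so bin
  identity is stable across windows).
* **GTE** $= -\sum_i p_i \sum_j p(j\,|\,i) \log_2 p(j\,|\,i)$, the
  conditional entropy of successive fixation-bin transitions. $p_i$ uses
  transition-source shares (the first $n-1$ fixations) so rows and weights
  describe the same sample; the difference from all-fixation shares vanishes
  for long sequences. Marginals are count-based, not duration-weighted.

Windows with no fixations have *missing* (not zero) entropy and duration
metrics — zero would conflate "no data" with "perfectly concentrated gaze" —
while a blink count of zero is a true zero. Stage means average usable
windows per metric, so denominators may differ across metrics. A participant
is retained only when at most **35%** of their windows across all four
stages are low quality, and (when an N-Back log is present) when every
N-Back fraction correct is strictly above **0.5**.

# NASA-TLX scoring

Six scales (mental, physical, temporal, performance, effort, frustration)
on the signed nine-point range $[-4, +4]$. The averaged answer inverts the
performance scale by negation — the natural mirror on a symmetric signed
scale; the instrument specifies inversion but no formula — giving
`mean(mental, physical, temporal, -performance, effort, frustration)`.
Raising any demand scale by one raises the average by $1/6$; raising
performance lowers it by $1/6$.

# Discrimination and coherence

**Expected-direction accuracy.** For each measure and each stage pair
(`HighwayDriving` vs `HighwayNback`, `UrbanDriving` vs `UrbanNback`,
`HighwayDriving` vs `UrbanDriving`), a subject scores 1 when their
within-subject difference of stage means has the predicted sign, 0
otherwise; ties score 0 because the rule is binary. Accuracy is the scoring
fraction over subjects with both values; subjects missing either stage are
excluded pairwise and N is reported per cell. Under a Gaussian
within-subject model with effect $\delta$ and per-stage noise $\sigma$,
accuracy converges to $\Phi\!\big(\delta/(\sqrt{2}\sigma)\big)$, which the
tests verify at $n = 500$.

The direction table is configuration, not code. Its defaults: fixation
duration and blink number higher on the highway and raised by the N-Back
task; saccade velocity lowered by load on either axis; SGE higher in urban
driving and lowered by the N-Back task; GTE higher on the highway, lowered
by the N-Back task on the highway but raised by it in urban driving; TLX
scales follow the load ordering (urban above highway, N-Back above plain
driving) with the raw performance scale reversed. Published accounts of the
highway–urban GTE direction are not fully consistent across analyses of
this design; the default follows the distribution-level result, and any row
can be overridden through `run_config(direction_table = ...)`.

**Spearman correlations** between each gaze metric and each TLX scale are
computed per stage and pooled, with tie-corrected ranks
(`stats::cor.test`), two-sided p-values, and strength bands (|ρ| < 0.3
weak, 0.3–0.7 moderate, > 0.7 strong). No multiple-testing correction is
applied by default (raw significance is reported); a `p_adjust_method`
switch is provided.

**Coherence** is Lin's concordance correlation coefficient
$\rho_c = 2 s_{xy} / (s_x^2 + s_y^2 + (\bar{x} - \bar{y})^2)$ (population
moments) between (1) rank-coded stages (lower-CL stage 0, higher 1) and
gaze metrics, (2) stages and TLX scales, and (3) gaze metrics and TLX
scales, pooling subject × stage observations within each pair. Because
$\rho_c$ penalises location and scale disagreement, raw bits against a
0/1 rank would be forced toward zero regardless of association; both
vectors are therefore min–max scaled to $[0,1]$ within the compared pair
before the coefficient is computed. Component significance uses a z-test
on $\tanh^{-1}(\rho_c)$ with $se = 1/\sqrt{n-3}$ — a Fisher-type
approximation that is conservative under independence (the exact Lin
variance is not used). Absolute values of significant components are
aggregated as mean/min/max; with no significant component the aggregates
are missing with `n_components = 0`.

# The synthetic cohort generator

`simulate_gaze_stage()` emulates what the analysis assumes about real
tracker output, with ground truth for every generated event:

* **Scan path.** Fixation targets are cells of an 8 × 8 lattice whose
  active subset has $m = \max(2, \mathrm{round}(\text{dispersion} \cdot
  64))$ cells in serpentine order; the fixation sequence follows
  $T = (1-\varepsilon) P_{cycle} + \varepsilon U$, a deterministic
  serpentine cycle mixed with uniform jumps. The uniform part excludes
  self-transitions, since a zero-amplitude "saccade" between two fixations
  in the same cell is unrecoverable by any detector;
  `expected_transition_entropy()` gives the analytic conditional entropy of
  exactly this kernel and is strictly increasing in $\varepsilon$.
  `dispersion` therefore controls stationary spread (SGE) and
  `regularity_eps` scan-path randomness (GTE), independently.
* **Lattice geometry.** Cells are spaced six entropy bins apart (5.625 cm ≈
  2.9° at 112 cm) and offset to bin centres, so generator cells coincide
  with detector bins and every inter-cell jump clears the 1°/sample saccade
  gate. Shrinking the lattice with dispersion instead would push jumps
  below the detector floor and silently merge truth fixations — the reason
  spread is encoded as *how many* cells are visited, not how far apart they
  sit.
* **Fixations** have lognormal durations (`fix_dur_mu`, `fix_dur_sigma` on
  log-ms), clamped to the 6–1200-frame detector range, with per-sample
  jitter uniform in ±0.25° per axis, so the worst inter-sample change
  (0.71°) never reaches the 1° threshold and the worst first saccade step
  stays above it.
* **Saccades** move linearly in plane coordinates over
  $d = \mathrm{clamp}(\min(\mathrm{round}(60/\text{gain}),
  \lfloor A/1.8 \rfloor), 2, 12)$ frames for amplitude $A$; the floor term
  guarantees every inter-sample step ≥ 1.8° before jitter, and measured
  velocity increases with `saccade_peak_gain`.
* **Blinks** are a Poisson process (`blink_rate`/min) of 6–12-frame
  closures placed inside sufficiently long fixations (6-frame margins), so
  each blink splits its host fixation in the ground truth exactly as the
  masking detector will. Gaze holds its last open-eye value during the
  blink; the frames stay tracker-valid by default (a regime switch can
  flag them invalid). The eyelid baseline is a slow sinusoid (period 13 s,
  amplitude 0.5) plus small white noise — the band-limited signal the
  IQR-derivative blink rule presumes.
* **Dropouts** flag frames invalid with probability `dropout_rate`
  (default 0.02 in the stage defaults).

`default_regimes()` encodes the ordinal between-stage pattern the analysis
targets (directions only — magnitudes are not calibrated to any dataset):
dispersion 0.35/0.25/0.85/0.60 and regularity 0.65/0.12/0.25/0.45 for
HighwayDriving/HighwayNback/UrbanDriving/UrbanNback, fixation-duration
medians 420/520/310/390 ms, saccade gains 30/20/24/17, blink rates
20/26/12/16 per minute, and latent TLX loads −1.5/1.5/0/2. The strong
highway regularity contrast is deliberate: windowed GTE estimated from
~60–80 transitions carries a downward sparse-row bias that grows with the
number of occupied cells, so ordinal recovery needs the true entropy gap to
dominate that bias. `simulate_cohort()` adds small per-subject parameter
jitters (individual differences), a subject TLX intercept (sd 0.8), TLX
noise (sd 1.0 on the latent scale before rounding), per-subject N-Back item
accuracy drawn from 0.70–0.95, and a randomised stage order per participant;
it stores a *plan* (seeds and parameters) rather than frames, and
`cohort_stage_frames()` regenerates any cell deterministically.

**What the generator does not emulate.** Real scenes impose structured,
task-driven scan paths, smooth pursuit on moving targets, head motion
coupled to steering, pupil dynamics, and non-stationary noise; the
generator has none of these. Passing recovery and discrimination tests
therefore demonstrates that the pipeline's thresholds, windowing, QC and
statistics are implemented correctly and recover known structure — not that
the thresholds are optimal for any particular tracker or scene.

# Numerical choices and problem sizes

Tolerances: parallel-ray test $10^{-9}$; geometry oracle agreement
$10^{-8}$ cm; entropy closed forms $10^{-9}$ bits. Ties: half-open windows
and bins; boundary frames of a saccade belong to the neighbouring
fixations; QC inequalities are strict exactly where the rules say "higher
than". Degenerate inputs: empty frame sets, windows without events,
all-tied accuracy inputs, constant CCC inputs and sub-minimum correlation
cells all return empty/missing results or informative errors rather than
fabricated values.

The shipped validation uses sizes chosen to make the statistics sharp at
interactive cost: 1000 random rays for the geometry oracle, 20 clean
300 s stages for event recovery (IoU ≥ 0.5 matching), 10 seeds × 3
dispersion levels for SGE monotonicity at 60 s, and a 50-participant
four-stage cohort at 300 s for the end-to-end discrimination check. The
whole suite runs in a few minutes on one core.

# Known limitations

* A single cyclopean gaze ray is assumed; binocular origins are not
  modelled.
* The pixel space of the entropy grid depends on `px_per_cm`; results in
  bits are comparable only under a fixed pixel scale.
* Fixation shares in the entropies are count-based; duration weighting is a
  plausible alternative the package deliberately does not implement.
* The CCC significance test is an approximation (see above); with very
  small cohorts its conservatism can suppress true components.
* Omnibus testing (RM-ANOVA/MANOVA, post-hoc families) is out of scope: the
  pipeline emits tidy tables that standard statistics facilities consume.
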