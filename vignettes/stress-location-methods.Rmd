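---
title: "Methods: environment-based stress location mapping for low-speed mobility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: environment-based stress location mapping for low-speed mobility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lmdstress)
```

## The problem and the model

Low-speed mobility devices (LMDs) — powered wheelchairs and comparable
single-occupant electric vehicles legally capped at 6 km/h — are driven on
sidewalks, in close contact with pavement texture, other road users, and the
width constraints of the built environment. The stressors that matter for
these users (vibration from rough surfaces, encounters with pedestrians and
cyclists, narrow passages) differ from those of walking or cycling, so
stress maps built for other modes transfer poorly.

`lmdstress` estimates *where* along a route stress is likely, from
environmental measurements alone, and provides the statistical machinery to
check those estimates against a physiological signal (heart-rate
variability, HRV). The pipeline is:

1. **Segment** the route into equal-length stretches by geodesic chainage
   and recover each segment's traversal window from the GPS trajectory.
2. **Quantify** each stress factor per segment (vibration RMS, unique-person
   encounters, minimum sidewalk width).
3. **Classify** each factor into intensity levels 1–3 and sum them into a
   Composite Stress Score (CSS), labelled Low / Moderate / High.
4. **Validate**: clean RR-interval series, compute per-segment time-domain
   HRV (SDNN, RMSSD, pNN50), z-score within participant, and correlate the
   across-participant segment means with CSS.

### Segmentation and boundary matching

Boundaries are placed every `interval` metres of cumulative great-circle
distance along the route polyline (spherical Earth, R = 6,371 km; the error
against an ellipsoid is far below GPS noise at city scale). Boundary 0 sits
at the route origin; a trailing remainder shorter than one interval is
discarded so all segments have equal length. The default interval of 100 m
guarantees at least 60 s of data per segment at the 6 km/h cap, the accepted
floor for reliable ultra-short-term HRV.

Each boundary is matched to the GPS fix at minimum geodesic distance
(earliest fix on ties), and the matched timestamps become segment
entry/exit times, used half-open `[entry, exit)` everywhere. Because a rider
traverses boundaries in order, matched times must be strictly increasing.
This is not automatic: on a loop the start boundary's globally nearest fix
can belong to the *end* of the ride. When the raw matches are non-monotone
the package re-matches all boundaries at once by a dynamic program that
minimizes the total match distance subject to strict time ordering, with a
per-boundary "unmatched" option costing the rejection radius (default 50 m,
generous against typical GPS accuracy). Segments adjacent to an unmatched
boundary are dropped.

### Signal conditioning

* **Environmental channels** are screened against the physical measurement
  ranges of the recording sensors (noise 30–130 dB, temperature 0–50 °C,
  humidity 0–95 %RH, wind 0.4–25 m/s, illuminance 0–20,000 lux); out-of-range
  samples are anomalous and removed. These channels are carried through but
  do not enter the default CSS, which uses the three factors above.
* **Acceleration** (100 Hz, y axis vertical under the mounting convention)
  is band-limited to 0.5–45 Hz and offset-corrected by subtracting the
  per-axis mean over a stationary period (supplied, or auto-detected as
  GPS speed < 0.1 m/s sustained ≥ 10 s). Vibration per second is the RMS of
  the vertical axis over non-overlapping 1 s windows; windows with under
  half the expected samples are set missing. The band-pass is realized as a
  cascade of 4th-order Butterworth high-pass and low-pass sections, each
  applied forward–backward (zero phase), with the signal mean removed first.
  A single 8-pole band-pass in transfer-function form is numerically
  unstable at a low edge of 1% of Nyquist — it leaked several m/s² of a
  constant input in our checks — while the cascade attenuates DC below 1e-6
  and passes a 10 Hz tone within 1%.
* **GPS** is resampled to a uniform 1 Hz grid. Gaps of at most `gap_max`
  (default 10 s, the adopted boundary between brief signal loss and an
  outage) are filled by great-circle interpolation between the flanking
  fixes, equally spaced in time; longer gaps stay missing and are flagged
  excluded.
* **Encounters** count distinct person IDs whose *first* appearance falls in
  the segment window, so nobody is counted twice across segments.

### Scoring

Factor values are oriented so larger means more stress (sidewalk width
enters with direction −1), then split at the 1/3 and 2/3
linear-interpolation quantiles of the pooled segment set; ties at a
threshold take the lower level (conservative and deterministic). All values
identical degenerates to level 1 everywhere, with a warning. Where accepted
absolute criteria exist, `classify_fixed()` implements value ≤ t1 → 1,
(t1, t2] → 2, > t2 → 3.

CSS is the sum of the levels. A sum of *n* terms each at least 1 ranges over
[*n*, 3*n*] — we use that structural range even though the score is
sometimes described as starting at 1. The label bands divide the range into
equal thirds; the band edges are resolved half-open (Low: CSS ≤ *n*,
Moderate: (*n*, 2*n*], High: (2*n*, 3*n*]) so that the two-factor worked
partition is ≤2 / 3–4 / 5–6 and, with three factors, a CSS of 6 is Moderate
and 7 is High. Raising any single factor level can never lower the CSS or
its label.

### RRI cleaning and HRV

The artifact chain runs ectopic → Hampel → quotient → interpolation:

* **Ectopic bounds**: intervals outside 300–1300 ms are masked (bounds
  survive).
* **Hampel**: within a sliding window of unmasked beats, the robust scale is
  σ = 1.4826 × MAD about the window median (1.4826 = 1/Φ⁻¹(0.75)); beats
  deviating more than 3σ are masked. Masked beats are excluded from all
  window statistics. Two numerical guards matter: a threshold floor of 5 ms
  handles MAD = 0 (a constant stretch flags nothing), and the window must
  hold at least 3 usable beats or the beat is left unjudged. The window
  *length* is a free parameter of this filter family; we default to 21
  beats because the MAD of an 11-beat window is noisy enough that ~3% of
  genuinely clean i.i.d. Gaussian beats get flagged, while 21 beats brings
  that below 2% and halves the reconstruction error on spike-corrupted
  synthetic series, at no cost to detection of isolated outliers. It
  remains configurable (`hampel_window`).
* **Quotient**: an interior beat differing by more than 10% from the mean of
  its two unmasked neighbours is masked; endpoints and beats with masked
  neighbours are untested.
* **Interpolation**: masked values are replaced by a cubic spline fitted
  over beat *index* (timestamps retained), evaluated at the masked
  positions, and clamped to the observed range of unmasked beats — the
  cubic can overshoot wildly (even below zero) when extrapolating through
  masked runs at the series edges. Removal fractions are reported per stage
  over the riding period; a participant losing more than 5% is flagged for
  exclusion, and any 60-s span losing over 20% is flagged unreliable.

SDNN is the sample standard deviation (N−1), RMSSD the root mean square of
successive differences, and pNN50 the percentage of successive differences
above 50 ms with N−1 pairs in the denominator; all three are invariant to
adding a constant to every interval. pNN50 is reported in percent. Indices
are z-scored per participant across segments (zero variance yields z = 0
with a warning), removing inter-individual baselines.

### Validation statistics

`spearman_bootstrap()` correlates per-segment CSS with the
across-participant mean z-score, resampling *segment pairs* (the
correlation's sampling unit) 5000 times for a percentile CI. The p-value is
an exact permutation value for n ≤ 10 without ties, otherwise the
asymptotic t approximation. Strength labels follow the conventional bands
(1.0 Perfect, ≥0.7 Strong, ≥0.4 Moderate, ≥0.1 Weak, 0 None); values in
(0, 0.1) fall between published bands and are labelled "Negligible"
(configurable). `detectable_rho()` inverts the Fisher-z power formula —
atanh(ρ) = (z₁₋α/₂ + z_power)/√(n−3) — giving ≈0.56 at n = 23, α = 0.05,
80% power: correlations below that are not reliably detectable at this
segment count.

`compare_segments()` contrasts selected segments within subject: Shapiro–Wilk
per segment gates between one-way repeated-measures ANOVA (all normal) and
the Friedman test; on omnibus significance each segment is compared against
the low-stress reference only (paired t or Wilcoxon signed-rank), Bonferroni-
adjusted over those comparisons. Fewer than 5 participants is refused;
zero-variance columns short-circuit to no test.

## The synthetic-ride generator

The generator exists so that every downstream stage is testable against
known truth. One master seed drives independent substreams per signal, so
identical configurations reproduce bit-identical rides.

* **Route**: a gently wobbled closed loop (2,350 m by default, giving 23
  whole 100 m segments) whose polyline length is converged to the requested
  length within 0.1%, landing just above it so the final boundary survives.
* **Motion**: per-second speeds ~N(1.25, 0.15) m/s clipped to the 6 km/h
  cap, preceded by a 30 s stationary lead-in (the offset-correction window,
  mirroring a pre-ride rest); boundary passage times are recorded as truth.
* **Stress profile**: per segment, three intensities in [0,1]. The default
  profile draws from well-separated values {0.1, 0.5, 0.9}, stratified so
  each factor's level counts line up with the tertile cut positions —
  without that stratification the quantile classifier and any absolute
  ground-truth rule disagree on boundary segments by construction, which
  would measure the test fixture rather than the pipeline. True factor
  levels are the tertile classification of the intensities (identical here
  to absolute thirds), and true CSS/labels follow by applying the scoring
  module itself.
* **Coupling**: vertical vibration is 0.5–45 Hz band-limited noise with
  σ = 0.05 + 0.8·intensity m/s²; encounters are Poisson with mean
  30·intensity unique persons per segment; sidewalk width is
  3.5 − 2.7·intensity m in 25 m pieces with ±0.1 m jitter.
* **RRI**: a standardized AR(1) fluctuation (lag-1 correlation 0.9) around a
  per-participant baseline (~N(900, 60) ms), scaled so the marginal SD
  equals the segment's SDNN target: 50 ms in Low segments, 30 ms in High
  (a 40% suppression), midway in Moderate. The autocorrelation is essential
  realism: white-noise RRIs have successive differences of √2·SDNN, which
  the 10% quotient filter flags at ~11% — real HRV is smooth at the beat
  scale. Artifacts are injected *after* the clean series is stored (1%
  ectopic replacements outside the 300–1300 ms bounds, 1% spikes of 15–35%
  relative change), so cleaning can be scored against an exact oracle.

What the generator does **not** emulate: real road-surface spectra (the
vibration is shaped noise, not pavement), correlated GPS multipath error
(noise is isotropic i.i.d.), circadian or exertion-driven HRV trends,
respiratory sinus arrhythmia structure beyond AR(1), and any visual scene.
Passing tests therefore demonstrate that the pipeline recovers the designed
couplings through realistic noise and artifacts — not that the couplings
hold in field data, which must be established observationally.

## Problem sizes and numerical conventions

The test suite exercises: label recovery and directional validation on 100
seeded rides each (23 segments; the directional check uses 32 simulated
participants per seed with the full cleaning chain on the HRV side and the
ground-truth CSS as the stressor); cleaning recovery on 100 corrupted
series; HRV oracle equivalence on 100 random series at 1e-9 relative
tolerance; omnibus type-I calibration on 1,000 null data sets (32 × 5); and
bootstrap CI coverage at n = 23 over 300 trials of 1,000 resamples against
a Monte-Carlo-widened 92–98% band. `scripts/acceptance.R` re-runs the main
computations at matching sizes (one full 32-participant study with 5000-rep
bootstraps, 20 rides for label recovery, 400 null simulations).

Conventions: WGS84 decimal degrees; all times are seconds on one unified
clock (timezone conversion happens at ingest via `tz_offset`); all windows
are half-open `[entry, exit)`; quantile thresholds pool all segments being
analyzed; equidistant matches and quantile ties resolve deterministically
(earliest fix, lower level).

## Limitations

Quantile-based levels are dataset-relative: the same physical environment
classifies differently inside different rides, which aids within-study
comparison but blocks absolute cross-study thresholds (`classify_fixed()`
is the escape hatch once criteria exist). The ground-truth recovery results
inherit the generator's separability assumptions. Bootstrap CIs at n = 23
are themselves noisy, and the Fisher-z power bound means only moderate-to-
strong correlations are detectable at this segment count. The spherical
Earth model is inappropriate beyond city scale.
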