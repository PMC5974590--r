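---
title: "Measuring eye-tracking data quality with gazeqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring eye-tracking data quality with gazeqc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazeqc)
```

## The problem

A remote eye tracker reports a point of gaze (POG) on the screen, but the
reported POG differs from the true one by a participant-specific
calibration error. Two components of data quality matter most for screen
experiments: **spatial accuracy** (the angular distance between true and
recorded POG) and **spatial precision** (the dispersion of recorded POG
samples during a stable fixation). Both degrade sharply in populations
who cannot follow instructions — toddlers move, look away, or fixate the
wrong thing — so per-participant quality must be measured, not assumed
from the vendor's data sheet.

`gazeqc` analyzes a calibration-verification procedure: after the
tracker's own calibration, five targets are shown one at a time for
2,000 ms each (four corner targets inset 480, 270 px from the screen
edges of a 1920x1080 display, one at center — roughly 16° and 0°
eccentricity at 60 cm), and the recorded gaze is compared with the known
target positions.

## Geometry

All metrics are expressed in degrees of visual angle. The display is
modelled by its resolution and physical size; when only a diagonal is
given, square pixels are assumed (explicit width/height override this).
The eye is assumed to sit on the perpendicular through screen center at
the participant's mean recorded eye-to-screen distance `d` (the tracker
reports per-eye distances per sample; the pipeline averages whichever
eyes are present). The per-axis angle of a pixel coordinate `p` is

\[ \theta(p) = \arctan\big((p - c)\,\mathrm{pitch} / d\big), \]

with `c` the screen-center coordinate, and the separation of two points
is the Euclidean combination of their per-axis angular offsets. This
convention is exact for the on-axis eye model, symmetric, and satisfies
the triangle inequality. No trigonometric convention reproduces the
conventionally quoted corner eccentricities of this layout (14.1° and
8.2° at 60 cm) exactly — under ours they come out at 13.99° and 7.97°, a
0.8–2.7% spread — so the geometry tests accept a 3% band rather than
forcing agreement with any particular published rounding.

Pixel coordinates are continuous, 0-based, origin top-left, x rightward,
y downward; a sample is on-screen iff `0 ≤ x < resolution_x` and
`0 ≤ y < resolution_y`.

## Sample validity

A sample enters analysis iff **(1)** at least one eye's validity code is
accepted, **(2)** gaze coordinates are present, and **(3)** the gaze
point is on-screen. Per-eye codes follow the common 0–4 vendor
convention; the default policy accepts only code 0 ("eye found with
certainty") and can be widened to `{0, 1}`. Missing numeric cells in
exports become `NA`, never zeros; the sentinel values treated as missing
(empty cell, `-1` for coordinates) are configurable because export
dialects vary and guessing silently would corrupt data.

## Fixation classification

When the export carries a vendor fixation index, events are adopted from
it (blocks sharing an index are merged with a warning; invalid samples
inside an event are discarded from its centroid). Otherwise an I-VT
velocity-threshold filter is applied:

| parameter | default | meaning |
|---|---|---|
| `velocity_threshold_deg_s` | 30 °/s | samples strictly below it are fixation candidates |
| `min_fixation_ms` | 60 ms | shorter events are discarded |
| `velocity_window_ms` | 20 ms | centered window for the speed estimate (~7 samples at 300 Hz) |
| `max_gap_ms` | 75 ms | longest bridged invalid gap (blink/dropout), no interpolation |
| `merge_max_angle_deg` | 0.5° | spatial consistency bound for bridging and merging |

Speed at a sample is the angular separation between the first and last
samples of the centered window divided by their time span; it is
undefined where the window contains an invalid sample. The 20 ms window
suppresses single-sample noise spikes that would otherwise register as
spurious saccades at 300 Hz.

Two design choices go beyond the bare threshold-and-duration rule, both
mirroring the merge stage of widely used commercial I-VT
implementations, and both controlled by `merge_max_angle_deg`:

* bridging an invalid gap additionally requires the gaze to resume
  within 0.5° of where it left off — a blink should not fuse two dwells
  at different locations into one "fixation";
* adjacent fixation fragments separated by at most `max_gap_ms` whose
  centroids lie within 0.5° are merged. At realistic noise levels a
  minority of within-fixation windows exceed 30 °/s by chance; without
  the merge these single-sample interruptions fragment one dwell into
  pieces shorter than 60 ms and the trial is spuriously lost.

A sample exactly at the threshold is non-fixation (strict `<`), for
determinism. Non-fixation samples are left as saccade/unclassified;
no saccade events are emitted.

## Per-trial metrics

A trial is valid when an eligible fixation exists: it must start at or
after trial onset (and before trial offset — later events belong to the
next trial), and may continue past stimulus offset. Among eligible
events the **longest** is selected — the longest fixation is the one
most plausibly intended for the target, whereas selecting the *nearest*
fixation would bias accuracy optimistically. Ties break to the earliest
event.

From the chosen fixation's valid samples:

* **accuracy** — the fixation location is the pixel-space mean of the
  samples (matching how exports define fixation coordinates), and
  accuracy is its angular separation from the target center;
* **SD precision** — per-axis, each sample coordinate is converted to an
  angle first, then the root-mean-square deviation from the mean angle
  is taken with population (1/n) normalization;
* **RMS precision** — per-axis root-mean-square of the n−1 successive
  angular differences. Pairs that straddle a discarded invalid sample
  are treated as adjacent ("bridged"); the per-trial count of bridged
  pairs is reported as a diagnostic so users can judge whether dropout
  inflated their RMS. (Skipping such pairs instead would discard data
  asymmetrically; either choice is defensible, so the one taken is made
  visible.)

Both precision measures need at least 2 valid samples and are otherwise
reported absent with a reason.

## Group rules and statistics

* **Outlier trials**: one pass over all valid trial accuracies pooled
  across the analysis group; trials above `mean + 1.5·SD` are flagged.
  Upper-tail only — an unusually *small* error is not an anomaly worth
  removing. The rule is deliberately not iterated: re-applying it to the
  survivors would keep shaving the tail.
* **Inclusion**: participants with zero valid trials are excluded ("no
  valid fixations"). A participant whose mean accuracy exceeds the group
  threshold (default 2°, a sensible review point for child groups) or
  more than half of whose valid trials were flagged goes to *review*,
  not automatic exclusion — a single 12° trial alongside four sub-2°
  trials usually means the participant looked elsewhere on one trial,
  and their data may still be usable.
* **Run comparison**: paired Wilcoxon signed-rank on participant-level
  means (accuracy, SD x/y, RMS x/y), over participants with valid data
  in both verification runs; pairing at the participant-mean level is
  stated in the report footnote. Fewer than 5 pairs flags low power.
* **Group comparison**: per measure, Shapiro–Wilk normality screen per
  group, Kruskal–Wallis omnibus, then pairwise two-tailed Mann–Whitney
  evaluated at a fixed corrected α = 0.008 (reproducing the fixed-α
  correction style common in this literature rather than a p-adjustment
  method). All tests use the standard implementations in `stats`; the
  test suite cross-checks them against exhaustive permutation and
  pair-counting oracles.

Reports annotate the vendor-claimed reference band (accuracy 0.4–0.9°,
RMS 0.04–0.15°) clearly labelled as a specification, never as data.

## The simulator

The synthetic generator exists so that every pipeline stage has known
ground truth. One session = five 2,000 ms trials at 300 Hz, target order
pseudorandom with the center target never first. Per trial the simulated
gaze holds its previous position for a uniform 100–300 ms latency,
relocates in a 30 ms linear ramp (fast enough to trip any sensible
velocity threshold), then dwells on the target displaced by the
participant's calibration offset. The offset is applied per-axis in
angle space, so the noise-free pipeline recovers exactly its norm.

Noise is per-axis Gaussian with lag-1 autocorrelation ρ (AR(1)), chosen
because it separates the two precision measures analytically:

\[ E[\mathrm{SD}] \approx \sigma, \qquad
   E[\mathrm{RMS}] = \sigma\sqrt{2(1-\rho)} . \]

`expected_metrics()` implements these, including the exact AR(1)
small-sample correction for the SD of an n-sample fixation. White noise
(ρ = 0) gives RMS/SD → √2; ρ → 1 gives smooth drift that looks precise
to RMS but not to SD.

Non-compliant trials replace the dwell with rapid scanning: mini-dwells
of 25–50 ms (below the 60 ms minimum, so they cannot form valid
fixations) at random locations up to 3° beyond the screen edge —
off-screen excursions are emitted as valid-eye samples with
out-of-bounds coordinates, exercising the off-screen invalidation rule.
Dropout marks samples invalid (validity code 4, coordinates missing)
with i.i.d. per-sample probability.

Cohort presets (`adult`, `school_age`, `toddler_18m`, `toddler_30m`)
draw per-participant offset magnitudes from a lognormal (CV 0.3) around
0.6°, 1.0°, 1.5°, 1.45° respectively, with noise sigmas near 0.10–0.22°
and toddler session-compliance 0.78/0.86 — a non-engaged participant
roams on every trial and is excluded for having no valid fixations,
emulating the roughly one-in-five toddler exclusion rate typical of this
age range. The preset magnitudes are chosen once for a clean qualitative
adult < school-age < toddler ordering, not to match any published
group's values (those derive from real recordings); the cohort manifest
records every drawn parameter so users can recalibrate presets to their
own population. Seeding uses one master seed from which per-participant
sub-seeds are drawn, so cohorts are byte-reproducible.

### What passing tests show — and what they do not

The simulator produces stationary AR(1) noise around piecewise-constant
intent. Real gaze data contain drift over the session, microsaccades,
smooth pursuit, head motion, asymmetric and heavy-tailed noise, and
tracker-specific filtering. Passing the recovery tests therefore shows
the *pipeline arithmetic* is right (metrics recover injected parameters;
rules fire exactly when contracted), not that any particular tracker or
population will match the presets. Test problem sizes are chosen for
desk-scale runs: 1,000-fixation oracle sweeps, 200-replicate noise
calibrations, 100 low-noise traces for the dwell-count property, and 50
replicate cohorts of 10 participants per group for the ordering check.

## Numerical conventions

* Timestamps are milliseconds (a flag accepts microseconds); duplicate
  timestamps are dropped keeping the first; exports round-trip numeric
  values through 17-significant-digit text bit-identically.
* Outlier SD uses the sample (n−1) estimator; metric SD inside a
  fixation uses population 1/n, per the standard definitions of each.
* Degenerate inputs: empty exports parse to empty recordings; a trial
  with no eligible fixation is invalid, not an error; a participant
  whose valid trials are all flagged as outliers keeps their inclusion
  decision but drops out of group means; all-zero paired differences
  report "no difference" (p = 1) instead of erroring.
* The fixed default viewing distance (60 cm) is used only when an export
  carries no distance data, and the choice is surfaced in the output.

## Known limitations

* Monocular-only dialects (separate left/right gaze columns) must be
  mapped to the two-eye average by the schema; the package does not
  reconstruct a better eye average itself.
* The I-VT event boundaries are not guaranteed to match any vendor's
  implementation sample-for-sample (vendor internals are undocumented);
  metrics are robust to small boundary differences because they use the
  longest fixation's bulk samples.
* No drift *correction* is attempted: when verification shows large,
  inconsistent error the defensible choice is exclusion, and the
  package's role is to quantify, flag, and report.
* Temporal accuracy and robustness (data-loss fraction beyond validity
  counts) are out of scope.
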