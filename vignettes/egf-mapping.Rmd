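---
title: "Electrographic flow mapping: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electrographic flow mapping: models, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egflow)
```

## The problem

Atrial fibrillation (AF) can be sustained by extra-pulmonary-vein focal
sources that drive fibrillatory conduction, and the organization of atrial
wavefront propagation reflects the health of the underlying substrate.
Electrographic flow (EGF) mapping estimates the wavefront propagation
vector field from 64-channel unipolar electrograms recorded with an
8-spline x 8-ring basket catheter, and summarizes it in two clinically
used quantities:

* **Source activity (SAC)** — a source is an origin of divergent flow; its
  activity is the percentage of 2-s segments in which it emanates flow.
  SAC at or above 25% marks a clinically significant source.
* **EGF consistency (EGFC)** — the mean modulus of the temporally averaged
  flow vectors across electrodes, in arbitrary units. Organized
  propagation gives long, stable vectors and high EGFC; fibrillatory
  conduction gives vectors that cancel over time and low EGFC.

Patients are phenotyped on the quadrants of (significant source present?)
x (EGFC at or above the cohort median?): Type I (no source, high EGFC)
through Type IV (no source, low EGFC).

## Pipeline and models

### Electrode geometry

The catheter is unwrapped onto a flat chart: spline index A–H on a
periodic x axis (A adjoins H), ring 1–8 on a bounded y axis, unit spacing
on both. Every electrode has exactly four neighbors; two artificial polar
electrodes, the per-sample means of ring 1 and ring 8, close the
neighborhood at the poles. The chart is an approximation — the true
basket is a deformed ellipsoid — and all distances below are chart
distances.

### Cleaning

Recordings are cleaned with zero-phase 4th-order Butterworth filters
(high-pass 0.5 Hz for baseline wander, low-pass 100 Hz for broadband
noise, optional 50/60 Hz notch), followed by ventricular far-field
removal: the far-field beat is detected on the cross-channel median
(atrial activity largely cancels in the median; the QRS, common to all
channels at zero lag, does not), an average beat template is built from
the median, and subtracted at every occurrence. The subtraction only
engages when the common mode carries at least a tenth of the median
channel RMS, so recordings without ventricular far-field pass through
untouched. Cleaning is idempotent to well under 1% RMS.

### Near-field contact score

Per 2-s segment, each channel's signal is decomposed against its four
neighbors by normalized cross-correlation over lags (windowed
normalization, N = half the segment). The best peak is a *conduction*
component only when its lag falls in the physiologic 5–50 ms window —
shorter lags are instantaneous (far-field) pickup, longer ones are too
slow for conduction. Both orderings of each pair are searched, because a
wavefront may reach either electrode first. When no conduction is found,
the *instantaneous* component is the mean zero-lag correlation with the
neighbors. The per-segment mask is 1 when the instantaneous ratio stays
below 0.3; the per-electrode mean of the mask is the summative near-field
score, and electrodes scoring below 0.7 are treated as non-contacting and
excluded from interpolation and EGFC. An alternative "caption" rule
(near-field only when conduction is present) is available as a
configuration option; it differs for silent channels, which the default
rule scores as near-field.

### Interpolation

Per time sample (after block-averaging to the frame rate), electrode
amplitudes are interpolated onto a raster with the two-dimensional
biharmonic Green's function g(r) = r²(ln r − 1), g(0) = 0: weights solve
G w = v, so the surface passes exactly through the data. The circular
spline axis is honored by replicating the nodes one period to each side,
and the raster itself is padded two grid units past the seam so that the
downstream flow estimator sees the periodic continuation rather than an
artificial boundary — without this pad, spurious divergence appears along
the seam meridian.

### Optical flow

Classic Horn–Schunck flow is estimated between consecutive frames
(central-difference spatial gradients on the frame mean, forward temporal
difference, the standard 1/6–1/12 neighborhood kernel). Per 2-s segment,
the raw instantaneous vectors at each contacting electrode's pixel are
averaged; opposing flows cancel, which is exactly what makes the segment
vector modulus a consistency measure. Consecutive pairs within a segment
are warm-started from each other (faster convergence toward the same
fixed point); the warm start is reset at segment boundaries so segments
stay independent.

### Sources

Per segment, candidate origins are lattice cells whose divergence
(central differences, periodic across splines, one-sided at the rings)
exceeds a threshold, is a local maximum, and whose surrounding vectors
point outward in at least 7 of the 8 directions. The candidate location
is refined by a focus-of-expansion least squares: the point minimizing
the squared normal distance to the surrounding flow rays, which recovers
a source that falls between lattice cells regardless of which cell wins
the local maximum. Candidates within one electrode spacing merge into a
single source across segments (single linkage); SAC is the percentage of
segments with a candidate.

### EGFC aggregation

Recording EGFC is the mean vector modulus over contacting electrodes and
segments (times an arbitrary-units constant kappa). Aggregation is an
unweighted mean at each level — recordings within a position, positions
within an atrium, atria within a patient — so that every mapped position
carries equal weight. Sinus-rhythm EGFC can be converted to the AF scale
by a linear map whose coefficients come from a separately published
calibration; they are not distributed here, and the conversion refuses to
run without them.

### Registry statistics

Group comparisons use one-tailed tests oriented along the observed
difference: a pooled two-proportion z (no continuity correction) for
proportions and a pooled-variance t for summary statistics; regression is
ordinary least squares with the F-test of the slope. These choices
reproduce all seven recomputable printed comparisons to three decimal
places from the bundled table of counts (`registry_report()`); one
printed value (0.017 for the de novo paroxysmal subgroup) recomputes to
0.018 under every test variant we tried and is flagged in the fixture
rather than adjusted.

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `sac_threshold` | 25 | % | clinical significance of a source |
| `inst_threshold` | 0.3 | – | far-field mask cutoff per segment |
| `score_threshold` | 0.7 | – | summative contact score cutoff |
| `highpass_hz` / `lowpass_hz` | 0.5 / 100 | Hz | cleaning band |
| `frame_rate` | 50 | frames/s | interpolated frame rate |
| `R` | 29 | px | raster resolution (0.25 grid units/px) |
| `alpha` | 0.5 | – | Horn–Schunck smoothness weight |
| `n_iter` | 100 | – | Horn–Schunck iterations |
| `tau_div` | 6 | (grid units/s)/unit | source divergence threshold |
| `tau_cov` | 0.875 | – | outward angular coverage |
| `kappa` | 1 | – | EGFC arbitrary-units scale |

The first three are the clinically published operating thresholds and are
not free: they define the method. The rest are implementation choices the
original system does not publish, and were fixed as follows.

* **alpha = 0.5, n_iter = 100.** On the amplitude scale of interpolated
  electrogram frames, alpha = 1 leaves the iteration visibly
  under-converged at 100 iterations: recovered speeds shrink to the point
  where organized and fibrillatory recordings become indistinguishable,
  and direction estimates can even invert. At alpha = 0.5 the iteration
  converges within the same budget and wave direction is recovered to a
  degree or two. Users who raise alpha should raise `n_iter` with it.
* **tau_div = 6, tau_cov = 0.875.** Calibrated on the synthetic
  generator: true focal sources produce divergence peaks of 15–20 in
  these units, planar propagation at most ~1.3, and fibrillatory
  transients 4–16 at sites that do not repeat. The defaults sit between
  the planar and focal ranges with a wide margin on both sides, and the
  stricter coverage requirement prunes transient quasi-radial patterns.
* **R = 29.** (R − 1) divisible by 7 puts every electrode exactly on a
  raster pixel; 29 gives 4x spatial oversampling at 0.25 grid units per
  pixel.

## What the synthetic generator emulates — and what it does not

`simulate_recording()` produces unipolar recordings under four regimes:
planar waves (organized propagation), intermittent focal sources
(radial activation from a fixed origin during a chosen fraction of 2-s
segments, quiescent otherwise), fibrillatory conduction (several
concurrent randomly seeded wavelets per beat, earliest wavefront wins,
with per-channel conduction jitter), and quiescence. Local deflections
are derivative-of-Gaussian biphasic waveforms (sigma 12 ms, ~1 mV);
cycle lengths are jittered beat to beat (8% SD) because real atrial
rhythms are never strictly periodic — and a perfectly periodic train
makes the conduction lag genuinely ambiguous (every cycle offset
correlates equally). Nuisance terms are a common-mode low-frequency QRS
far-field, per-channel baseline wander, white noise, and non-contact
electrodes that carry only a smoothed common far-field plus noise.

The generator is deliberately phenomenological. It does not model ionic
or monodomain biophysics, true 3-D basket deformation, anatomical
structures (veins, appendages), meandering rotors, or spatially
correlated noise. Consequently, passing tests demonstrate that the
pipeline recovers the dynamics it claims to recover under controlled
conditions with known truth — not that it would reproduce any specific
clinical measurement. Clinical EGFC magnitudes in particular live on an
arbitrary scale; all validation here uses orderings, rates, and
recovered ground truth, never absolute EGFC values.

## Numerical choices and degenerate inputs

* Biharmonic systems with (near-)coincident nodes get a small ridge on
  the diagonal and a warning.
* Zero-energy cross-correlation windows return 0 and channels with no
  non-zero conduction pair get a conduction ratio of 0.
* The focus-of-expansion solve falls back to the winning lattice cell
  when the normal-equation system is ill-conditioned (as for near-planar
  flow) or when the solution strays more than 1.5 spacings from the peak.
* Trailing partial segments are dropped; a recording shorter than one
  segment is an error.
* Boundary thresholds are inclusive where the method's definitions are:
  SAC exactly 25 is significant, a near-field score exactly 0.7 is good
  contact, EGFC exactly at the cohort median is "high".
* Even-count cohort medians take the midpoint of the two central values.

## Validation sizes

The test suite and the acceptance script validate at desk scale: focal
runs use 20-s recordings (10 segments, so SAC is quantized in 10-point
steps and a half-active source reads exactly 50%), planar negative
controls 12 s, EGFC-ordering pairs 8 s, near-field runs 8 s, and the
end-to-end cohort 30-s recordings per position. Thirty segments-per-
recording (the full 60 s) runs unchanged, only slower; the shorter
lengths raise, not lower, the bar for the fibrillatory negative controls
because chance co-location of wavelet origins weighs more when there are
fewer segments.

## Known limitations

* The 2-D chart ignores basket deformation; distances near the poles are
  distorted relative to the real geometry.
* Horn–Schunck underestimates speeds (quadratic smoothness prior), so
  flow magnitudes — and hence EGFC — are meaningful as relative, not
  physical, velocities.
* The near-field rule scores an electrically silent channel as
  near-field (its instantaneous ratio is 0); the caption-mode rule is
  provided for users who prefer conduction-positive evidence of contact.
* Source detection reports origins of divergent flow only; it does not
  distinguish focal firing from micro-reentry seen end-on, and phase
  singularities (rotors) are out of scope.
* The voltage-map color classifier assumes the standard clinical palette
  (purple above 0.5 mV, grey below 0.1 mV, blue-to-red in between);
  palettes are configurable but not auto-detected.

## A minimal run

```{r example, eval = FALSE}
cohort <- generate_cohort(4, seed = 1, duration = 30)
run <- run_pipeline(cohort)
run$phenotypes$table
registry_report()
```
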