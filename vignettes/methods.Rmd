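---
title: "Methods: diastolic function from phase-contrast CMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diastolic function from phase-contrast CMR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcmr)
```

This vignette documents the algorithms in `pcmr`, the assumptions behind
them, the package-level design decisions, and the known limitations.

## Data model

A `pc_series` pairs a modulus (magnitude) stack with a decoded velocity
stack over one retrospectively ECG-gated cardiac cycle, `P` phases of
`H x W` pixels. Phase `i` (0-based) is acquired `i * frame_interval` ms
after the R-wave; `cycle_length = P * frame_interval`. Velocities are
signed through-plane values in cm/s and must satisfy `|v| <= venc`; samples
exactly at the encoding bound are counted as possibly aliased and are kept,
never unwrapped — phase unwrapping would silently alter data, so the count
is surfaced instead.

Conventions used throughout the public interface: 0-based `(row, col)`
pixel coordinates with pixel centres at integer positions, 0-based phase
indices, and a pixel belongs to an ROI when its centre lies inside the
drawn shape. Polygon vertices at half-integer positions avoid boundary
ambiguity.

## Flow segmentation

The user draws one rough ROI around the flow of interest on a single phase
(mid-cycle for transmitral flow, first phase for aortic). The automated
part is:

1. **Reference phase.** The ROI mean-velocity curve over the cycle is
   computed; the reference phase is the one with the greatest absolute mean
   velocity, and its sign is the sign of the flow of interest.
2. **Initial detection.** On the reference phase, the flow is the biggest
   8-connected area of pixels of that sign within the ROI dilated by 3
   pixels (the dilation tolerates jet motion across the cycle without
   leaking to the other valve).
3. **Centre-of-mass propagation.** The component's centre of mass is
   propagated phase-by-phase toward both ends of the cycle. At each phase
   the biggest same-sign component containing the propagated point is
   kept; if the point lands in background (e.g. the valve has closed), the
   largest component with a pixel within 2 px of the point is accepted,
   and failing that the phase is left empty and the previous centroid is
   carried forward. Components below 4 pixels are treated as noise specks.

### Noise floor and hysteresis

The textbook rule "biggest connected area of pixels with the flow's sign"
is exact on noise-free data but ill-posed on noisy data: a zero-mean noise
field gives every background pixel a random sign, and under 8-connectivity
a random sign field percolates (the site-percolation threshold of the Moore
neighbourhood, about 0.407, is below the 0.5 sign probability), so the jet
merges with a system-spanning background component at any realistic noise
level.

`segment_flow` therefore detects components above a robust per-phase noise
floor. The noise level is estimated as `1.4826 * MAD(v, centre = 0)` over
the whole phase image (the flow occupies a small fraction of the field, so
the median absolute deviation reflects noise, not signal). The signed
velocity field is smoothed with a 3x3 box filter, core components are
pixels above 2 standard deviations of the smoothed noise, and the final
mask is the surrounding 1-standard-deviation component that contains the
selected core (hysteresis: the high threshold decides *which* structure is
flow, the low threshold recovers its full extent). When the estimated noise
is zero both thresholds are zero and the procedure reduces exactly to plain
sign-connectivity, so noise-free results are unchanged.

### Assumptions

- The flow of interest keeps one velocity sign for its whole duration.
- The rough ROI contains the jet at the reference phase and, after 3 px of
  dilation, at every phase where the jet exists.
- Background velocity offsets (eddy currents) are small relative to the
  jet; a constant offset can be modelled in the phantom but is not
  corrected in real data.

## Velocity and flow-rate curves

Per phase, with `w` the signed velocity rectified so the flow of interest
is positive:

- **Maximal velocity** is the average of pixel values above 95% of the
  in-mask maximum. Averaging the top 5% band instead of taking the single
  maximum suppresses the upward bias a pointwise maximum has under noise.
- **Mean velocity** is the in-mask mean; the **flow rate** is the mean
  velocity times the segmented area (`ml/s = cm/s x cm^2`), so
  `q = v_mean * area` holds at machine precision by construction.

Temporal landmarks never come from single samples. Each wave limb's
40–70%-of-peak portion — the most linear part of a filling or ejection
limb — is fitted by least squares (band samples plus the exact
piecewise-linear crossings of the 40% and 70% levels) and extrapolated to
the time axis. On an exactly triangular limb sampled on the phase grid this
recovers the vertex exactly, which is the basis of the closed-form
acceptance checks.

From these landmarks:

- **DT** — from the Ef peak to the extrapolated end of the Ef wave.
- **IVRT** — extrapolated filling onset minus extrapolated ejection end
  (from the aortic flow-rate curve); clamped to 0 with a warning if the
  extrapolations cross.
- **FV** — trapezoidal integral of the non-negative flow rate over the
  filling period, whose *extrapolated* bounds deliberately extend beyond
  the sampled zero crossings so the triangle area is integrated in full.
- **E and A** — the two highest local maxima of the maximal-velocity curve
  in the diastolic window (from ejection end to cycle end), constrained to
  be at least one sixth of the cycle apart; the *earlier* peak is E, by
  time of occurrence rather than amplitude, so E/A < 1 patterns are
  handled correctly. Ef and Af are the same detection on the flow-rate
  curve. With only one admissible peak (e.g. fused E-A at high heart
  rates), A-dependent parameters are reported as `NA` with a warning.

Landmark times are taken from flow-rate waves rather than maximal-velocity
waves: flow rates average over the whole segmented area and are less
noise-sensitive.

## Myocardial velocities

The mitral annulus reverses direction within the cycle, so sign-based
tracking cannot apply. Instead every pixel inside a rough LV ROI
contributes its full-cycle velocity profile as a feature vector, and
k-means (k = 7, squared-Euclidean distance, unnormalized profiles)
partitions the ROI into tissue classes. The myocardial mask is the biggest
8-connected spatial component over all cluster labels.

Two implementation points matter in practice:

- **Restarts.** k-means is seeded and takes the best of 50 random
  initializations by within-cluster sum of squares. With only a few
  restarts the optimizer can settle in a worse local optimum that splits
  the myocardium across two labels, fragmenting the connected component
  the next stage relies on; 50 restarts reliably reach the lower-inertia
  solution at a cost of well under a second.
- **Within-mask presmoothing.** The 95%-of-maximum rule is reused for the
  myocardial "maximal" curves (the least-surprise choice, flagged here),
  but applied to pixel values smoothed with a 3x3 box *inside the mask*.
  On the thin, nearly uniform myocardial band the raw rule selects the
  upper tail of the noise and overestimates E′ by several percent;
  averaging neighbours first is unbiased in expectation on a uniform
  field. The flow curves do **not** presmooth, because a transmitral jet
  is strongly peaked and smoothing would bias its centre value low.

E′ detection works on the rectified global maximal-velocity curve: the
diastolic direction is the sign of the mean myocardial velocity during the
filling window, and E′ is the earlier of the two highest admissible local
peaks in that window (the same pair rule as E/A, so an E′ smaller than A′
is still attributed correctly). The filling window comes from the flow
analysis when available; standalone, it is derived from the last
zero-crossing of the mean-velocity curve preceding its largest diastolic
excursion — the time the annulus reverses direction.

Segmental curves are provided as four angular quadrants about the cavity
centre (45°–315° boundaries, rotatable by a configurable reference angle,
labels configurable) because the anatomical orientation of a given
acquisition is not knowable from the pixel data alone.

## Digital phantoms

`make_flow_phantom()` builds a 128 x 128, 60-phase, 15 ms series (venc
180 cm/s, 1.9 mm pixels): a transmitral orifice (12 mm radius) carrying a
parabolic spatial profile whose centre follows a triangular E/A waveform
(defaults E = 80, A = 60 cm/s, DT = 185 ms, IVRT = 78 ms), and an
opposite-signed aortic orifice (10 mm radius) active in systole, plus
seeded Gaussian noise (default 2 cm/s). Requested timings snap to the
15-ms phase grid — the reported truth is the *snapped*, actually generated
value (DT 180 ms, IVRT 75 ms). Because the spatial profile is separable
from the waveform, the true peak filling rates and filling volume have
closed forms, which the truth list reports along with the exact noise-free
masks.

`make_myo_phantom()` builds a 64 x 64, 45-phase, 20 ms tissue series (venc
20 cm/s): an annular myocardial ring (17–27 mm radii) carrying an S′/E′/A′
triangular waveform (defaults 8.5, 11.3, 6 cm/s, E′ at 560 ms), a cavity
with a biphasic parabolic blood-pool signal, a static background gradient,
and seeded noise (0.5 cm/s).

These sizes and values are package choices for a desk-scale validation
target, not measurements; they are chosen so one full analysis runs in
seconds on one CPU. The phantoms deliberately do *not* emulate partial
volume effects, view-sharing temporal blur, spatially varying eddy-current
offsets, aliasing wraps, or anatomy in the modulus images — they validate
the analysis chain, not the MR physics.

`perturb_roi()` jitters ROI vertices uniformly within a given number of
pixels (seeded), emulating a second operator for reproducibility studies.

## Cohort statistics

- **Overlap** between two masks is reported as the Dice coefficient
  (x100); two empty masks score 100. Dice was chosen over Jaccard because
  inter-operator overlap percentages in this field are customarily Dice;
  Jaccard is available as an option.
- **Variability** of a repeated measurement is `100 |x1 - x2| / mean`.
- **Mann-Whitney**: U from midranks; the two-sided p-value is exact for
  pooled samples of at most 12 without ties, otherwise a normal
  approximation with tie and continuity corrections.
- **Pearson** correlation with the least-squares line.
- **ROC**: thresholds swept at midpoints between consecutive sorted unique
  values plus one beyond each extreme, in whichever orientation puts AUC
  at or above 0.5; AUC itself is the rank-based pairwise concordance
  probability. The operating point maximizes Youden's J (sensitivity +
  specificity − 1) — chosen because it weighs both error types equally and
  needs no prevalence assumption — with ties broken by higher accuracy,
  then lower threshold, making the report deterministic.

## Determinism and open-question decisions

Every stochastic step (phantom noise, k-means initialization, ROI
perturbation) is seeded, and seeded runs are bit-reproducible. Decisions
the problem statement leaves open, and the choices made:

- **Connectivity** is 8-neighbour everywhere (a diagonal-touching jet
  stays one object).
- **Tie-breaks** are deterministic: equal-size components resolve by the
  lexicographically smallest (row, col) centroid; equal-Youden thresholds
  by accuracy then threshold value.
- **Aliasing** is surfaced, never unwrapped.
- **DICOM** ingestion is not implemented (no DICOM parser is available to
  this package); `load_pc_series(format = "dicom")` fails with a pointer
  to the NIfTI-plus-JSON container route, which round-trips exactly.

## Limitations

- At high noise (5% of venc on the flow phantom) the mean diastolic Dice
  against the phantom truth plateaus near 86–88% rather than approaching
  100%. This is a property of the validation target, not a fixable defect
  of the detector: the truth mask is the full parabolic-jet support at
  every active phase, including wave feet where the signal is near zero,
  and an oracle that sweeps every possible per-phase threshold against the
  truth caps near 76% mean Dice there. The hysteresis detector's
  connectivity information beats plain thresholding but cannot recover
  sub-noise signal. Parameter recovery is much less affected because the
  95% rule and the limb fits concentrate on the well-detected wave cores.
- IVRT at default phantom noise is biased a few ms low: noise at the wave
  feet slightly advances the extrapolated filling onset. The recovered
  value stays within one frame interval of the configured truth.
- The segmentation assumes one dominant flow of one sign inside the
  (dilated) ROI; valve regurgitation in the same window would need a
  narrower ROI.
- Tissue venc (20 cm/s) leaves no headroom for fast blood; real
  annular-level series alias in the cavity. The analysis never reads
  cavity pixels after clustering, but the aliased-sample count should be
  checked on real data.
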