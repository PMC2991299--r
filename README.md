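# pcmr — diastolic function analysis from phase-contrast cardiac MR

`pcmr` evaluates left-ventricular diastolic function from velocity-encoded
(phase-contrast) cine cardiovascular MR. From a pair of through-plane
velocity series — one across the mitral valve (blood flow) and one at the
level of the mitral annulus (myocardial tissue) — it extracts the standard
diastolic indices with minimal operator input: each series needs only a
rough region of interest drawn on a single cardiac phase.

What it computes:

- **Transmitral flow**: semi-automated segmentation of the flow pattern on
  every cardiac phase, maximal-velocity and flow-rate curves, and the
  parameters E, A, E/A, the peak filling rates Ef, Af, Ef/Af, the filling
  volume FV, the deceleration time DT and the isovolumetric relaxation time
  IVRT (timed against the aortic flow curve).
- **Myocardial velocities**: k-means clustering of per-pixel velocity
  time-profiles isolates the myocardium; the early diastolic annular
  velocity E′ and the ratio E/E′ follow from its velocity curves.
- **Cohort statistics**: Dice overlap and variability for reproducibility
  studies, Mann-Whitney group comparison, Pearson correlation, and ROC
  analysis with the Youden-optimal operating point.
- **Digital phantoms**: seeded flow and tissue phantom generators with
  exact ground truth, used for all validation in this package.

## How it works

A transmitral or aortic flow pattern is segmented starting from the rough
ROI: the reference phase is the one with the highest mean ROI velocity
magnitude; the flow there is the biggest connected area of pixels with the
flow's velocity sign; and its centre of mass is propagated phase-by-phase
toward both ends of the cycle, each step keeping the biggest same-sign
component containing the propagated point. On noisy data, components are
detected above a robust per-phase noise floor with hysteresis (see the
methods vignette) — with zero noise this reduces exactly to plain
sign-connectivity.

"Maximal" velocity per phase is the average of pixel velocities above 95%
of the in-mask maximum, a noise-robust maximum. Landmark times (filling
onset/end, ejection end) come from least-squares lines fitted to the
40–70%-of-peak portion of each wave limb, extrapolated to the time axis, so
DT, IVRT and FV do not depend on any single noisy sample.

The myocardium cannot be tracked by velocity sign (the annulus reverses
direction mid-cycle), so each pixel's full-cycle velocity profile is
clustered with k-means (k = 7, seeded); the myocardial mask is the biggest
spatially connected cluster. E′ is the first of the two highest local peaks
of the rectified maximal-velocity curve during the filling period.

## Worked example

Everything below runs in a few seconds on one CPU, entirely from the
built-in phantoms.

```r
library(pcmr)

## a seeded transmitral/aortic flow phantom with known truth
ph <- make_flow_phantom(phantom_config("flow"), seed = 1)
ph$series
#> pc_series (flow): 60 phases of 128 x 128 pixels
#>   frame interval 15 ms (cycle 900 ms), venc 180 cm/s, pixel 1.9 x 1.9 mm

## rough ROIs: a box around each valve, drawn on one phase
mitral <- roi(30, rbind(c(69.5, 53.5), c(69.5, 74.5),
                        c(90.5, 74.5), c(90.5, 53.5)))
aortic <- roi(0, rbind(c(30.5, 54.5), c(30.5, 73.5),
                       c(50.5, 73.5), c(50.5, 54.5)))

fa <- analyze_flow(ph$series, mitral, aortic)
fa
#> Transmitral diastolic parameters:
#>   E = 79.4 cm/s (t=585 ms)   A = 61.1 cm/s (t=810 ms)   E/A = 1.30
#>   Ef = 180.5 ml/s  Af = 136.6 ml/s  Ef/Af = 1.32
#>   FV = 31.7 ml   Ef/FV = 5.69 1/s
#>   DT = 181 ms   IVRT = 63 ms
#>   timings: ejection end 429 ms, filling 493-869 ms

## the phantom was generated with E = 80, A = 60, DT = 185, IVRT = 78
## (the last two snap to the 15-ms phase grid: 180 and 75 ms)

## myocardial phantom: annular ring with E' = 11.3 cm/s
mph <- make_myo_phantom(phantom_config("myo"), seed = 1)
lv <- roi(0, list(centre = c(32, 32), semi_axes = c(17.5, 17.5)), "ellipse")
mp <- analyze_myocardium(mph$series, lv, seed = 3, E_velocity = fa$params$E)
mp
#> Myocardial longitudinal velocities: E' = 11.5 cm/s (t=560 ms)
#>   E/E' = 6.88
#>   myocardial cluster: 384 pixels

## segmentation accuracy against the phantom truth
overlap_percentage(mp$myocardial_mask, mph$truth$ring_mask)
#> [1] 100
```

A command-line front end covers the same pipeline on files
(`inst/cli/pcmr`): `pcmr phantom`, `pcmr segment`, `pcmr flow-params`,
`pcmr myo-params`, `pcmr cohort`. Series travel as NIfTI stacks with a JSON
sidecar; `write_pc_series()` / `read_pc_series()` round-trip exactly.

## Validation and reproducing results

- `tests/testthat/` — unit tests plus `test-acceptance.R`, which checks
  parameter recovery, segmentation fidelity, ROI-perturbation
  reproducibility, myocardial recovery, brute-force-oracle agreement of the
  statistical primitives, and a closed-form toy-curve limit. Run with:

  ```r
  testthat::test_dir("tests/testthat", package = "pcmr",
                     load_package = "installed")
  ```

  One known shortfall is kept deliberately visible: at a noise level of 5%
  of venc the mean diastolic Dice stays near 86–88%, below the 95% aimed
  for, because the phantom's truth mask includes the full jet support even
  at near-zero wave amplitude (see the methods vignette).

- `scripts/acceptance.R` — writes the headline quantities as JSON:

  ```sh
  Rscript scripts/acceptance.R --seed 1 --out acceptance.json
  ```

- `vignettes/methods.Rmd` — the algorithmic methods, assumptions and
  limitations in detail.

All analyses are deterministic given their seeds.
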