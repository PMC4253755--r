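# lvecho

Automatic detection of end-diastole (ED) and end-systole (ES) frames in 2D
echocardiographic image sequences, by measuring left-ventricular (LV) volume
in *every* frame.

Accurate EDV, ESV, stroke volume, ejection fraction and cardiac output all
depend on picking the right ED/ES frames, which is usually done visually or
from an ECG channel. `lvecho` needs only the images: it segments the LV blood
pool in each frame with an edge-stopped level-set active contour, converts
each contour to a volume by single-plane disk summation, and reads ED and ES
off the per-cycle extrema of the volume–time curve — ED and ES sit on the two
iso-volumic plateaus where ventricular volume is maximal and minimal.

**Who it is for:** researchers in cardiac image analysis who need a tested,
scriptable reference pipeline for volume-curve-based ED/ES detection, and a
self-validating synthetic phantom to benchmark segmentation and detection
against exact ground truth.

## The model in brief

The endocardial border is the zero level set of a field Φ(x, y, t), negative
inside the cavity, evolved by

    Φ_t = −(v0 − ε κ) · exp(−α |∇(G_σ ∗ I)|) · |∇Φ|

a balloon speed v0 regularized by curvature κ, multiplied by an
edge-stopping factor K1 = exp(−α E_image) that freezes the front on intensity
edges (E_image is the gradient magnitude of the Gaussian-smoothed frame).
After convergence the contour is relocated to the subpixel ridge of E_image
along local normals. Volumes use the single-plane method of disks about the
contour's principal axis; indices follow

    SV = EDV − ESV,  EF = SV/EDV × 100%,  CO = SV × HR

with HR taken from the detected cycle length (no ECG required). A validation
layer compares estimated and reference readings: MAE/MSE/MRE/RMSE, ordinary
least squares, Bland–Altman limits of agreement, and a paired t-test.

See `vignettes/lvecho-methods.Rmd` for the full account of the model,
parameters, numerics and limitations.

## Worked example

Generate a speckled beating-ventricle phantom (three cycles, EDV 120 mL,
ESV 50 mL, so the true EF is 58.33%), run the whole pipeline, and compare:

```r
library(lvecho)

phantom <- generate_phantom(phantom_params(rng_seed = 7))
phantom
#> <lv_phantom> 128x128 px, 3 cycles x 20 frames @ 25 Hz, EDV 120 / ESV 50 mL (EF 58.33%)

result <- analyze_sequence(phantom$sequence, seed = c(64.5, 64.5), n_cycles_hint = 3)
result
#> <lv_cycles> 3 cycle(s); ED frames: 1, 20, 40; ES frames: 10, 30, 50
#>   mean over 3 cycle(s): EDV 118.9 mL, ESV 49.7 mL, SV 69.2 mL, EF 58.20%, HR 75.1 bpm, CO 5199 mL/min
```

The true ED frames are 1, 21, 41 and the true ES frames 10, 30, 50: under
10% multiplicative speckle the detector lands within one frame of each, and
the recovered EF (58.20%) is 0.13 points from truth. `result$indices` holds
the per-cycle table; `autoplot(result$curve, result$detection)` draws the
volume curve with the detected extrema;
`plot_frame_contours(phantom$sequence$frames[[1]], result$contours[[1]])`
overlays a segmented border on its frame.

Validating a cohort of estimated EFs against reference readings:

```r
study <- simulate_ef_study(n_cases = 44, noise_sd = 2, seed = 1)
agreement_report(study$estimated, study$reference)
#> <lv_agreement> EF (%), n = 44
#>   MAE 1.2986  MSE 2.9680  MRE 0.0254  RMSE 1.7228
#>   regression: slope 0.999  intercept 0.233  r 0.988
#>   Bland-Altman: bias 0.158  LoA [-3.244, 3.559]
#>   paired t-test: p = 0.5496
```

`tidy()` and `glance()` return these as tibbles; `autoplot()` draws the
regression and Bland–Altman panels.

## Command line

A thin CLI wraps the same functions (installed under `exec/`):

```sh
lvecho simulate --out frames/ --seed 7
lvecho segment  --frames frames/ --seed-point 64.5,64.5 --out contours/
lvecho analyze  --contours contours/ --spacing 1 --fps 25 --cycles 3 --out report.json
lvecho validate --estimated est.csv --reference ref.csv --out agreement.json
```

`simulate` writes zero-padded PNG frames plus `ground_truth.csv` and
per-frame truth contours; `segment` writes per-frame contour CSVs and a
segmentation log; `analyze` writes a JSON report and `volume_curve.csv` with
ED/ES labels; `validate` reads `case_id,value` CSVs and writes the agreement
report. Configuration (level-set parameters, disk count, smoothing, phantom
settings) comes from a YAML file via `--config`.

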