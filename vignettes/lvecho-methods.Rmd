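---
title: "Measuring left-ventricular volumes and detecting ED/ES frames with lvecho"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring left-ventricular volumes and detecting ED/ES frames with lvecho}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvecho)
```

## The problem

Global indices of left-ventricular (LV) function — end-diastolic and
end-systolic volume (EDV, ESV), stroke volume (SV = EDV − ESV), ejection
fraction (EF = SV/EDV × 100%) and cardiac output (CO = SV × HR) — all hinge on
knowing *which frames* of a 2D echocardiographic cine loop are end-diastole
(maximal filling, at AV-valve closure) and end-systole (maximal contraction).
In routine practice these frames are picked visually, or from an ECG channel
that is not always recorded alongside the images. `lvecho` implements a purely
image-based alternative: segment the LV blood pool in *every* frame, build the
volume–time curve, and read ED and ES off its per-cycle extrema, which sit on
the two iso-volumic plateaus of the cardiac cycle.

The pipeline is

1. **Segmentation** — an edge-stopped level-set active contour per frame
   (`segment_frame()`, `segment_sequence()`),
2. **Volume quantification** — single-plane disk summation of each contour
   (`disk_volume()`, `build_curve()`),
3. **ED/ES detection and indices** — per-cycle extrema of the volume signal
   (`detect_ed_es()`, `cardiac_indices()`),
4. **Agreement statistics** against a reference reading
   (`agreement_report()`: MAE/MSE/MRE/RMSE, ordinary least squares,
   Bland–Altman limits of agreement, paired t-test).

A synthetic beating-ventricle phantom with exact analytic ground truth
(`generate_phantom()`) makes every stage testable without patient data.

## The level-set model

The endocardial border is the zero level set of a scalar field
$\Phi(x, y, t)$, negative inside the cavity, evolved by

$$\Phi_t = -F(\kappa)\, K_1\, |\nabla \Phi|,$$

with a composite speed made of two ingredients:

* $F(\kappa) = v_0 - \varepsilon\,\kappa$ — a constant *balloon* speed $v_0$
  (positive: the front inflates from a seed placed inside the cavity) minus a
  curvature regularization $\varepsilon\,\kappa$, where
  $\kappa = \nabla\!\cdot\!\left(\nabla\Phi / |\nabla\Phi|\right)$;
* $K_1 = e^{-\alpha\,E_{\text{image}}}$ — the edge-stopping factor, with
  $E_{\text{image}} = |\nabla (G_\sigma * I)|$ the gradient magnitude of the
  Gaussian-smoothed frame. $K_1$ is 1 in homogeneous tissue and decays to
  zero on intensity edges, freezing the front at the border.

Numerics: explicit Euler with Godunov upwinding for the advective part,
central differences for the curvature part ($|\nabla\Phi|$ floored at
$10^{-8}$, $\kappa$ clamped to $\pm 1\,\text{px}^{-1}$), and periodic
reinitialization to a signed-distance function by exact geometric
redistancing against the marching-squares zero contour. Evolution stops when
the fraction of grid points whose $\Phi$-sign changed over the last 5
iterations falls below `converge_tol`, or at `max_iters`. Updates can be
restricted to a narrow band (`band_width`); band and full-grid runs converge
to the same contour well within a pixel.

### Subpixel edge relocation

A purely edge-stopped speed has a known localization bias: the speed decays
on the *inner* flank of the gradient ridge, so the front freezes
systematically about one pixel inside the true border. The classical remedy —
a gradient-attraction (geodesic) advection term — is deliberately outside
this package's scope, whose speed is exactly $F(\kappa) K_1$. Instead, after
convergence the contour is relocated along its local normals to the maximum
of $E_{\text{image}}$ within ±`snap_search` pixels (offsets smoothed along
the contour to resist speckle). On the phantom this removes an
otherwise ~10% systematic underestimate of both EDV and ESV and a ~4-point
EF inflation. Disable with `snap_to_edge = FALSE` to inspect the raw front.

### Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `sigma` | 1.5 | px | Gaussian scale of the image energy; larger = more speckle suppression, wider edge ridge |
| `edge_gain` | 55 | — | $\alpha$ in $e^{-\alpha E}$; large enough that the weakest true edge still freezes the front within the iteration budget |
| `v0` | 1 | px/time | balloon speed (sign sets inflate/deflate) |
| `eps_curv` | 0.35 | — | curvature weight; suppresses speckle-leak bumps, smooths the front |
| `dt` | 0.35 | time | explicit step; CFL bound `dt * max speed <= 0.5` px enforced |
| `reinit_every` | 20 | iters | redistancing period |
| `converge_tol` | 1e-4 | — | sign-change fraction over a 5-iteration window |
| `snap_search` | 3 | px | half-width of the subpixel edge search |

The defaults were chosen on the default phantom so that (i) the front never
leaks through the weakest border point within `max_iters`, and (ii) the
curvature term holds the high-curvature apex/base tips where blur weakens the
edge. They are starting points for real data, not constants of the method.

## From a 2D contour to a volume

Clinical volume curves are computed from single-plane contours; the package
uses single-plane disk summation: slice the polygon into `n_disks` strips
perpendicular to its principal axis (the longest chord of the 256-point
resampled contour); a strip of width $w$ whose slicing line intersects the
polygon over total chord length $d_i$ contributes $\pi (d_i/2)^2 w$. This
treats the cavity as a solid of revolution about its long axis — exact for a
sphere and for the phantom's prolate spheroid, and the standard single-plane
convention when only one view is available. `n_disks = 20` is conventional;
doubling it changes phantom volumes by well under 1%. Non-convex slices sum
their intersection segments.

## ED/ES detection

Local maxima of the volume signal are ED candidates, local minima ES
candidates (run-length encoding, so exact plateaus resolve to their first
frame — ED is conventionally the frame at AV-valve closure onset, i.e. the
*start* of iso-volumic contraction). Same-type peaks closer than
$0.6\,n/\text{cycles}$ frames keep only the more extreme one; strict ED→ES
alternation is enforced; each ED is paired with the ES that follows it before
the next ED. Unpaired trailing peaks are dropped. Three robustness
refinements, all off or inert on clean signals:

* **Boundary frames** are admitted as extrema only if an interior extremum of
  the opposite type exists (a strictly monotone curve is "no complete
  cycle") *and* the boundary value is within 10% of the signal range of the
  global extremum of its type (a clip truncated mid-ejection does not donate
  a false ES).
* **Plateau grouping** (`plateau_tol`, default 1.5% of the signal range):
  contiguous frames within the tolerance of a detected extremum count as one
  iso-volumic plateau, resolved to its first frame — the measured-volume
  generalization of the exact-tie rule.
* **Median prefilter** (`median_window`): a running median applied before
  peak finding. Medians suppress single-frame volume jitter from speckle
  while leaving plateaus and their onsets untouched. `detect_ed_es()`
  defaults to 1 (off) so single-frame extrema are honoured exactly;
  the segmentation pipeline (`analyze_contours()`) defaults to 3 because
  measured volumes jitter by a few mL.

Heart rate comes from the detected ED-to-ED cycle length (no ECG needed);
the last cycle's span is taken to end one past the final frame, exact when
the clip ends on a cycle boundary. An `hr_bpm` override exists for
single-cycle clips. Multi-cycle indices are summarized by their arithmetic
mean (`glance()`).

## The phantom: what it emulates, and what it does not

`generate_phantom()` renders a hypoechoic elliptical blood pool (fixed long
axis, default 70% of the grid height) in brighter myocardium. Per frame the
short axis is set so the prolate-spheroid volume $\tfrac43\pi a b^2$ follows
a piecewise-smooth periodic profile with the qualitative shape of the
ventricular volume diagram: a flat plateau at EDV (iso-volumic contraction,
10% of the cycle), rapid-then-reduced ejection, a flat plateau at ESV
(iso-volumic relaxation), rapid-then-reduced filling. The profile is pinned
exactly to EDV and ESV once per cycle, and the designated ED/ES frames are
the plateau onsets. Frames are blurred (`blur_sigma`, emulating the
point-spread function) and multiplied by `1 + speckle_sigma * eta` with
standard-normal `eta` — a convenient stand-in for speckle, not Rayleigh
statistics. Defaults: 128×128 px at 1 mm/px, 3 cycles of 20 frames at 25 Hz
(~0.8 s per beat, HR 75), EDV 120 / ESV 50 mL (EF 58.33%), intensities
0.15/0.70, `speckle_sigma` 0.10.

Because the cavity is a solid of revolution, the disk-summation volume of the
exact contour equals the analytic volume — the phantom is self-validating.
What passing on the phantom does **not** show: robustness to real apical-view
anatomy (mitral annulus, papillary muscles, trabeculae), attenuation and
shadowing, probe motion, Rayleigh speckle, or genuinely low-contrast walls.
The phantom validates the *contracts* of the pipeline, not clinical accuracy.

## Agreement statistics

`agreement_report()` compares estimated and reference readings across cases:
MAE, MSE, RMSE; MRE as the mean relative error $|e-r|/|r|$; ordinary least
squares of estimated on reference with Pearson r; Bland–Altman bias and
bias ± 1.96 × sample SD (n − 1) limits of agreement; and a two-sided paired
t-test (p = 1 by convention when all differences are exactly zero; p = 0 in
the degenerate limit of a nonzero constant difference).
`simulate_ef_study()` draws a cohort of reference EFs uniformly and adds
Gaussian measurement error — the shape, not the content, of a clinical
validation study.

## Numerical choices and degenerate inputs

* Pixel centers at integer coordinates, origin top-left, x = column,
  y = row; contours are counterclockwise simple polygons (tibbles with
  `x`, `y`).
* Temporal propagation initializes each frame from the previous converged
  field shifted 2 px inward, so the balloon always re-approaches the border
  from inside even when the cavity contracts between frames (fastest
  per-frame contraction of the default phantom is ~1.3 px).
* Principal-axis ties break on the smallest starting vertex index; disk
  slicing lines that meet a vertex use a half-open crossing rule.
* Degenerate inputs error early and descriptively: contours with fewer than
  3 vertices or zero extent, collapsed or border-touching fronts (with the
  frame index), empty seed masks, CFL violations (with the admissible `dt`),
  even smoothing windows, monotone volume curves, zero EDV.
* Problem sizes used throughout the tests and the reproduction script —
  a 128×128 grid, 3 cycles × 20 frames, 44-case simulated studies — keep a
  full pipeline run around a minute on one core while leaving every contract
  observable at realistic scale.

## Known limitations

* The detection convention reports the *first* frame of a measured plateau;
  under heavy speckle the reported ED/ES can sit one frame off the true
  plateau onset.
* HR (hence CO) of the final cycle assumes the clip ends at a cycle
  boundary.
* The subpixel snap assumes the true border is the nearest energy ridge
  within `snap_search` px of the converged front; gross segmentation
  failures are not rescued by it.
* Volumes assume rotational symmetry about the long axis (single-plane disk
  method); biplane or 3D reconstruction is out of scope.
* AVI/DICOM ingestion is out of scope; sequences enter as PNG/TIFF frame
  directories or multi-page TIFF (`read_sequence()`).
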