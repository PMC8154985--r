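---
title: "Models and methods behind brainsweep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind brainsweep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainsweep)
```

This vignette documents the scientific model behind each module, the
parameters that matter (with units and defaults), the numerical choices,
and the limits of what the synthetic tests establish.

## The acquisition model

An electrically tunable lens (ETL) placed upstream of the x/y scanner
shifts the focal plane as a nonlinear, monotone function of its drive
current. The acquisition we model sweeps the focus *continuously*: a
sawtooth ramps the normalised depth `z*(t) = t / T_cycle` from 0 to 1 over
`n_planes` counted frames (default 30 frames at 30 Hz, so one volume per
second), then resets. Because the focus moves during each frame, the frame
is not a plane: a row at fraction `r` of the slow axis sits at

    z(frame, row) = z_range * (frame + row / n_rows) / n_planes

so consecutive frame starts are `z_range / n_planes` apart (6 µm for a
180 µm volume over 30 planes) and the last row of a frame is
`z_range / n_planes * (n_rows - 1) / n_rows` ≈ 6 µm deeper than its first.
Row-level timing within the resonant line is ignored: across one line the
focus moves by roughly 12 nm, orders of magnitude below the axial PSF.

### LUT calibration

Calibration measures pairs (drive current `I`, focal shift `z`). Depths are
remapped to `z* = (z - z_min)/(z_max - z_min)` and `I(z*)` is fitted with a
degree-5 polynomial by **unconstrained least squares** (`fit_lut()`). Two
deliberate choices:

- *Least squares, not interpolation.* With 8 points and degree 5 the two
  differ; we keep least squares so the residual RMS is a meaningful quality
  metric of the calibration, and the endpoint identities
  `I(0) ≈ I_min`, `I(1) ≈ I_max` are verified facts (within 3× the residual
  RMS) rather than enforced constraints.
- *No extrapolation.* `current_at()` refuses `z*` outside `[0, 1]`: the
  polynomial has no physical meaning outside the calibrated range.

The sawtooth generator (`generate_sawtooth()`) emits one cycle of
`(t, z*, I)` samples at the driver's update cadence (default 3 ms, hence
333 samples of a 1 s cycle). The physical 6–12 ms settling after the reset
step can be flagged (`settling_dead_time = TRUE`, marking samples in the
first frame) but is off by default, treating the reset as instantaneous.

## PSF metrology

Bead stacks are measured by the classic chain: crop around the bead,
*reslice* along the chosen axis, *average-project* the other two axes, and
summarise the resulting 1D profile with

    FWHM = 2 * sqrt(2 * ln 2) * sigma.

`sigma` is by default the **background-subtracted intensity-weighted SD**
of position (moment method), matching the idea of taking "the standard
deviation of the fluorescence profile"; a Gaussian least-squares fit is
available (`method = "gaussfit"`) as a cross-check. Numerical choices that
turned out to matter:

- *Background* is the median of the profile's outer 20% on each side. For
  this to be an actual background, the crop window must be wide relative to
  the spot: the default crop is ±6σ (hence the bead generator keeps beads
  ≥7σ from stack borders). With a ±3.5σ window the tails still contain real
  signal and the moment σ is biased low by 4–6%.
- *Noise rectification.* After background subtraction, weights are clamped
  at zero; with noise, the rectified tail noise inflates the second moment
  (at profile SNR ≈ 40 this is a +20% σ bias). The moment method therefore
  keeps only the contiguous above-threshold support around the peak
  (threshold = 2× the tail MAD) and **undoes the resulting truncation
  analytically**, dividing by the variance of a standard normal truncated
  at ±u, `u = sqrt(-2 ln(threshold/peak))`. With this, median recovery
  error across σ = 0.5–17 µm at SNR 20 is under 2% (the acceptance
  criterion allows 5%).

FOV extent is a linear fit of stage travel against bead pixel position,
extrapolated over the pixel range (`measure_fov()`); it resolves a planted
3% FOV change to better than 1%.

Absolute instrument values (e.g. lateral FWHM growing from ~0.5 to ~1.3 µm
across the defocus range) are properties of real hardware; the package only
demonstrates *recovery of known synthetic parameters*, not those numbers.

## Preprocessing

- `deinterleave()`: frame `k` belongs to plane `k mod n_planes`; trailing
  incomplete volumes are dropped and logged, and an initial window (default
  60 s in pipeline configurations; the lens drifts thermally early in a
  session) is discarded in whole volumes.
- `motion_correct()`: rigid per-frame registration by phase
  cross-correlation against the mean image (reference choice is
  configurable; the mean is the default because synthetic motion is
  zero-mean), refined to subpixel precision with a local matrix-multiply
  DFT upsampling (default ×10). Planted integer shifts are recovered
  exactly on noise-free scenes; 0.5 px shifts are recovered within 0.2 px.
  This is a deliberate self-contained stand-in for suite2p-class
  registration — same algorithm family, no external dependency — adequate
  because the synthetic motion model is rigid.
- `running_average()`: centred mean, default window 3 frames, shrunken
  windows at the edges. Edge shrinkage perturbs the trace mean by an
  O(window/n) term (for window 3 exactly
  `((y₂−y₁)+(y_{n−1}−y_n))/(6n)`); the tests assert this closed form rather
  than pretending exact conservation.
- `noise_floor()`: mean of per-segment SDs over (by default 16)
  pre-stimulus segments.

## Segmentation

The built-in detector replaces an external segmentation toolchain (whose
classifier and manual curation are out of scope): Gaussian-smooth the
temporal mean image (σ = cell_diameter/4), keep local maxima above
`median + threshold · SD`, enforce a minimum separation of one cell
diameter (6 µm — the typical nuclear diameter — so maxima closer than that
merge into the brighter one, which is logged), and grow disk ROIs of half a
cell diameter with contested pixels assigned to the nearest centroid. ROIs
on a plane never share pixels, and detection count is non-increasing in the
threshold. Externally produced ROI tables can be imported from CSV
(`read_rois()`), which is the route for real suite2p output.

## Response analysis

The looming stimulus geometry is closed-form: a dot of diameter `d` at
screen distance `D` subtends `θ = 2·atan(d/2D)` (9.5° for 5 mm at 30 mm;
79.6° for 50 mm at 30 mm, within 0.3% of the commonly quoted 79.4°). The
mean expansion rate is the final angle over the expansion duration.

Regressors: each presentation epoch is a binary waveform, convolved
causally with a **normalised exponentially decaying kernel**
`h[k] ∝ exp(-k/(τ·rate))`, τ defaulting to 3.5 s (the lower end of the
3.5–4.1 s decay range of the nuclear reporter; configurable). The kernel is
normalised to unit *sum* so convolution preserves the waveform's area;
unit-peak normalisation is available as an option. The default analysis
uses one *pooled* regressor gathering all presentations plus an intercept;
a per-presentation orthogonal basis is available. Note on pooling scores in
the multi-regressor mode (max over per-regressor β/MSE): in simulation the
max-pooling inflates the null distribution's tail (a multiple-comparisons
effect over 10 regressors) and markedly *worsens* planted recovery, which
is why the pipeline default remains the pooled regressor.

Each trace is fitted by OLS; the responsiveness **score is β/MSE** — large
when the trace follows the regressor strongly *and* cleanly. Every fit is
checked against an explicit normal-equations oracle at 1e-9 in the test
suite. A noiseless exact fit reports MSE 0 and score +Inf (always
selected); MSE below 1e-20 of the trace's mean square is treated as 0 to
make the sentinel reachable in floating point. Selection flags the
`ceiling(fraction · N)` top scores (top 5% of 47,992 gives 2,400), with
ties at the cut broken deterministically by trace index. No ΔF/F conversion
is applied before fitting; the score is invariant to trace offset (the
intercept absorbs it) and the β and MSE scale together under gain changes.

`zscore_events()` supports the pixel-wise analysis mode: traces are
z-scored against baseline windows and local maxima with z > 5 (default)
are events. An entirely constant trace trivially yields no events; a flat
baseline on a varying trace is an error (the z-score is undefined).

## Clustering

Selected response profiles are grouped by agglomerative clustering under
**Ward's minimum-variance criterion with squared Euclidean (L2) distance**,
cut at k = 4 (the number of motif groups typically reported for looming
responses; configurable, and the merge tree is exported so the cut is
auditable). Traces are z-scored per trace by default so motif *shape*
rather than amplitude drives the grouping; raw clustering is available.
The implementation delegates the agglomeration to `stats::hclust(d²,
"ward.D")`, whose merge heights are exactly twice the within-cluster
sum-of-squares increase; the package reports heights as the ΔSS itself,
and the tests verify merge-by-merge equality against a brute-force Ward
oracle on small instances plus direct ΔSS recomputation. Cluster labels
are renumbered in order of first appearance, making the labelling
deterministic for a given input order; with tied dissimilarities the merge
order is inherited from `hclust` (deterministic but not necessarily the
lowest-index pair).

## The synthetic world

The generator emulates the statistics of the real acquisition, with every
free parameter documented here:

- **Brain**: cells placed by rejection sampling with a hard 6 µm minimum
  centre distance (nuclei do not overlap). 5% of cells are responsive by
  default, split over 4 motifs.
- **Reporter kinetics**: single-exponential decay, τ = 3.5 s; unit-peak
  kernel, so an event of amplitude `a` adds `a · photon_gain` counts at its
  peak. Baseline 20 counts, gain 100 counts per unit ΔF/F, Poisson noise by
  default (photon-counting detection).
- **Spontaneous activity**: Poisson events at 0.01 events/s (~0.6
  transients/min) of amplitude 0.5 ΔF/F. Neither value is published for
  this preparation; they were chosen, once, as typical of sparse
  spontaneous activity in larval zebrafish and are free configuration.
- **Evoked responses**: per presentation, with probability 0.8, a
  responsive cell fires its motif's burst; per-cell amplitude is log-normal
  with median 1.5 ΔF/F (the selected top-quantile population consists of
  strongly driven cells by construction). The four motifs are: a
  fast-adapting burst (events of decreasing amplitude over the first half
  of the 17 s loom), a sustained response (uniform events across the
  epoch), a slow-rising response (events in the last 40%), and a
  habituating burst (fast-adapting shape, amplitude ×0.85 per trial —
  moderate habituation at 150 s inter-stimulus intervals). Exact kinetic
  parameters are free configuration; none are published.

  A note on why the motifs are bursts rather than single spikes: the β/MSE
  statistic *saturates in amplitude* for responses whose shape mismatches
  the regressor — the cell's own unexplained transient dominates the MSE,
  so a stronger mismatched responder scores lower, not higher. An early
  single-spike motif library made strong fast-onset responders structurally
  undetectable by the very statistic the pipeline uses. Multi-spike bursts
  integrated through the 3.5 s reporter are both the physiologically
  realistic picture of a looming response and a world in which the planted
  5% is recoverable (F1 = 0.96–0.98 across seeds; the acceptance criterion
  is ≥ 0.9).
- **Rendering**: frames in plane-major order; each cell contributes a 2D
  Gaussian at its (x, y), weighted by `exp(-dz²/2σ_z²)` of its distance to
  the focus *at its own row* (so the tilt is honoured); σ profiles may be
  functions of depth to emulate defocus broadening. Rigid planted motion
  and Poisson noise are optional. The caller chooses the lateral σ to
  represent PSF ⊗ nucleus; the default pipeline uses 1.5 µm.

What a green test does **not** establish: the generator has no scattering,
no bleaching, no non-rigid motion, no neuropil contamination, no
correlated (network) spontaneous activity, and Gaussian optics rather than
a diffraction model. Recovery results certify the pipeline's internal
consistency on its stated forward model, not performance on real tissue.

## Pipeline and reproducibility

`run_pipeline()` chains the stages and reports per-stage counts plus
recovery metrics against the ground truth. Two modes: `"trace"` (default)
analyses the simulated traces directly — the realistic configuration for
whole-brain work, where rendering a 30-minute 1024 × 512 × 30 stream
(≈ 10¹² voxel samples) is not feasible in a test budget, and segmentation
of real data is delegated; `"imaging"` renders a (reduced-geometry) stream
and runs the full de-interleave → register → smooth → detect → extract
chain, and is exercised in the test suite. All randomness derives from a
single root seed split per stage, so a rerun of the same configuration is
byte-identical — asserted in the acceptance tests at the file level.

## Known limitations

- The detector is intensity-based and static; dim or overlapping nuclei
  merge (logged), and no activity-based (suite2p-style) detection is
  attempted.
- Motion correction is rigid and per-plane; non-rigid tissue deformation is
  out of scope.
- `k` for the clustering is a user choice; no model selection is provided,
  only the exported dendrogram.
- The β/MSE score has the amplitude-saturation behaviour described above
  for shape-mismatched responses; this is a property of the published
  statistic itself, faithfully reproduced.
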