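---
title: "Tracking nuclei and Golgi bodies, and quantifying cell polarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking nuclei and Golgi bodies, and quantifying cell polarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ngvtrack)
```

## The problem

Adherent cells polarize before they move: the Golgi apparatus repositions
to the prospective leading side of the nucleus, and the nucleus elongates
along the direction of travel. Measuring when each of these internal
rearrangements happens — across thousands of cells, over a day of imaging —
requires tracking two organelles per cell in two fluorescence channels and
binding them into per-cell records.

`ngvtrack` implements that measurement chain. A two-channel time-lapse
stack (nuclei in one channel, Golgi in the other, one frame every few
minutes) goes in; what comes out are identity-stable trajectories for both
organelles, one-to-one nucleus–Golgi pairings, and the polarity and
motility statistics built on them: the apolar nucleus orientation, the
nucleus–Golgi vector (NGV), the truncated standard deviation of angle
samples, speed components relative to a substrate axis, the mean squared
displacement, the gyration-tensor anisotropy, and the velocity
autocorrelation function with its persistence-time fit.

The package also contains a first-class synthetic-movie generator with
complete ground truth. Every stage of the pipeline is validated against it,
and all the numbers quoted below are computed by the package's test suite
or acceptance script, not transcribed from elsewhere.

## Pipeline stages and their assumptions

### Brightness/contrast normalisation

Long live-cell movies drift in intensity (photobleaching, lamp drift), so
each frame is normalised from its own statistics: the pixel-intensity
histogram (256 bins) is fitted with a Gaussian by least squares, which
locks onto the background mode because background dominates the pixel
count. The adjustment window runs from `n_low` fitted standard deviations
below the mean to `n_high` above it and is mapped linearly onto the full
intensity range, saturating outside.

`n_low` and `n_high` are per-dataset (indeed, per-channel) choices. The
shipped `adjust_params()` defaults (1, 3) are display-normalisation
values. For detection, `n_high` should place the top of the window near
the *signal* level, not the background tail: with background noise of SD
sigma and objects ~60–80 sigma above background, windows of `n_high = 30`
(nuclei) and `n_high = 60` (Golgi) keep signal and background separable
after rescaling, which is what the pipeline defaults use. If the fit fails
(constant or grossly non-Gaussian frames) the sample mean/SD are used and
the result is flagged `converged = FALSE`.

### Nucleus segmentation

Nuclei are bright filled ellipses: global Otsu threshold, connected
components, and a per-component ellipse from second central moments. The
orientation is the major-axis angle, treated as apolar on [0°, 180°). Two
size gates apply: `min_area` (default 50 px²) removes debris, and
`max_area` (default 400 px² at the default 0.8 µm/px scale, roughly twice
the typical nucleus footprint) removes merged blobs formed when two nuclei
touch. A merged blob's centroid belongs to neither cell, so discarding it
and letting the tracker's gap memory carry both identities through the
contact loses less information than keeping it. Watershed splitting of
touching nuclei is out of scope.

### Golgi segmentation

The Golgi is dim, irregular and fragmented, so its stage is different:
a hard intensity cutoff keeps every bright pixel; single-linkage
clustering groups pixels whose chain distances stay within
`sensitivity × frame diagonal`; clusters under `min_cluster_px = 3`
pixels are discarded as noise; and a largest-first merging pass
reassembles fragments into whole Golgi bodies. The largest remaining
cluster computes its convex hull and absorbs every cluster whose nearest
hull-vertex distance is within `merge_distance`, recomputing the hull
until nothing more is absorbed; it then leaves the pool and the next
largest repeats. Ties in size break deterministically (row-major order of
the first pixel); degenerate hulls (< 3 distinct or collinear points) fall
back to the raw point set.

Two scale choices matter. The published sensitivity 0.1 is deliberately
permissive — fragments of one Golgi must land in one chain — but its
cutoff grows with the frame diagonal, so for large fields densely seeded
with cells the user should shrink it until the cutoff sits between the
fragment scatter and the inter-cell spacing; the synthetic benchmark at
0.8 µm/px uses 0.006 (cutoff ≈ 17 px ≈ 13 µm). `merge_distance` should
likewise exceed the fragment scatter and stay well below the cell spacing
(default 25 px = 20 µm). When two cells' Golgi genuinely overlap the
merger cannot tell them apart — a limitation accepted by design.

### Linking with gap memory

Detections are linked frame to frame in the cost-minimising tradition of
standard particle tracking: candidate links are limited to
`max_displacement` (default 15 px/frame, ~3× a fibroblast step at 5-min
cadence), and the per-frame assignment minimising total squared
displacement — with a non-match option costing `max_displacement²` — is
found exactly per connected component of the candidate graph by
branch-and-bound. Because fluorescence blinks, an unmatched track stays
eligible for re-linking for `memory = 10` frames before its identity is
retired; the value 10 is the validated choice for 5-minute fibroblast
movies and applies to both channels. Interior gaps are filled by straight
lines (the shortest in-filling) and flagged; endpoints are never
extrapolated; orientations are never interpolated — only observed frames
contribute angles.

### Nucleus–Golgi pairing

For every nucleus–Golgi trajectory pair the mean centroid distance over
their co-visible frames is tabulated (normalised by the frames the Golgi
is visible, so brief visibility is not penalised), entries beyond
`max_pair_distance` (default 40 px) are discarded, and a global
best-first pass commits the smallest remaining distance, removes both
members, and repeats — so a Golgi contested by two nuclei goes to the
nearer one and the loser defers to its next choice. The result is
one-to-one and fixed for the movie.

Before pairing, the pipeline drops *stub* trajectories — segments observed
in fewer than a quarter of the movie's frames by default
(`min_track_length = NULL`). Ephemeral segments are mostly artifacts of
transient proximity (two organelles merging for a few frames produce a
short mid-point track) and carry too little evidence for a stable
identity; the quarter-movie rule was chosen on a synthetic validation
movie by sweeping thresholds and inspecting the precision/recall
trade-off of the resulting pairings, which is the same
tune-on-a-test-set workflow the segmentation parameters assume. All
trajectories, stubs included, still reach the trajectory statistics and
the output tables.

## The statistics

### Apolar angles and the truncated standard deviation

All orientations are axial: θ and θ+180° are the same axis, so angles live
on [0°, 180°). The plain standard deviation of such a sample depends on
where the seam falls — a tight cluster straddling 0°/180° looks maximally
dispersed. The truncated standard deviation removes the seam dependence:
for every integer reference shift s = 0…179° the sample is shifted,
re-wrapped, and its SD computed; the smallest SD over shifts is the
spread, and the mean of the optimally shifted sample (mapped back) is the
mean orientation. The spread is then calibrated affinely so that a
uniform sample reads 52° and a perfectly aligned one 0° — the two anchor
values that define the scale (a uniform sample's raw SD is
180/√12 ≈ 51.96°, so the calibration factor is within 0.1% of unity).
Values near 52° mean no alignment; small values mean tight alignment with
the mean axis. The statistic is invariant (to the 1° grid) under rotation
of the whole sample, which the test suite checks property-style.

### Trajectory statistics

Speeds are frame-to-frame displacements of the gap-filled nucleus
trajectory; |v_x| and |v_y| are reported in the *wrinkle frame* — the
coordinate system rotated so a chosen substrate axis (e.g. the wrinkle
direction of a patterned substrate) is +x. The gyration tensor of a
trajectory is the time-covariance of its positions; its diagonal ratio
R_xx/R_yy, ensemble-averaged as a ratio of means, reads 1 for isotropic
exploration and >1 for motion channelled along x. The VACF is the mean
dot product of unit step vectors at increasing lags (zero-length steps
are skipped; lag 0 is 1 by construction); a least-squares line through
log C_vv over the positive values up to 600 minutes (10 h, beyond which
the curve is noise) gives the persistence time as −1/slope, flagged
undefined for non-decaying curves. Group comparisons use Kruskal–Wallis
with pairwise Wilcoxon post hocs, Bonferroni-multiplied and capped at 1,
with significance marked at 0.05 and 0.01.

## The synthetic generator

The generator emulates the statistical structure the pipeline assumes,
with full ground truth (positions, ellipses, fragment centers, visibility
flags, pairings):

* **Motion** — a heading-persistent random walk: the heading angle
  diffuses with variance 2·Δt/τ per frame, which makes the ensemble VACF
  an exact exponential with decay time τ (`persistence_time`, default
  240 min — the ~4 h persistence typical of fibroblasts). Step length is
  `mean_speed × Δt` (default 0.5 µm/min); `anisotropy` scales x-steps, so
  the gyration ratio scales as its square. Positions reflect at the
  domain borders.
* **Orientations** — axial von Mises (von Mises on doubled angles):
  concentration 0 is the uniform apolar law; large concentrations align
  all cells with the x axis. Orientations are fixed per cell — the
  generator emulates population alignment statistics, not in-place
  nuclear rotation.
* **Golgi** — each labeled cell's Golgi centroid sits `ngv_offset`
  (10 ± 2 µm) from the nucleus along an axially drawn angle (either sense
  of the axis with equal probability); 4 ± 1 fragments scatter around it
  with SD 3 µm and ride rigidly with the cell. `labeled_fraction`
  (default 0.4) reproduces partial transfection.
* **Blinking** — i.i.d. per-frame signal loss (p = 0.1) with dark runs
  capped at `blink_max = 10` frames by construction, the worst case the
  default memory parameter must absorb.
* **Rendering** — nuclei as anti-aliased filled ellipses with a mild
  interior falloff, Golgi fragments as small Gaussian blobs, plus
  additive Gaussian background noise; every frame's noise is seeded
  independently of access order, so movies are bit-reproducible.

Defaults describe one concrete imaging regime: 100 cells in a
1976 × 1976 px field at 0.8 µm/px (the scale of an 8 µm camera pixel
behind a 10× objective), one frame per 5 minutes for 288 frames (24 h).
The field size puts 100 cells at 4000 cells/cm², a typical seeding
density for this kind of experiment. The pixel pitch is a stated
assumption, not a measured value; physical metadata always come from the
configuration, never from image files.

One deliberate exception: statistics-only studies (no rendering) use a
larger motion domain (8000 × 8000 px) for the trajectory ensembles.
Confining a 24-hour trajectory to a camera-sized *reflecting* box
shortens its apparent persistence time by about a quarter — an artifact
of the boundary model, since real cells leave the field of view rather
than bounce off it. With the open field the VACF fit recovers a 240-min
persistence time to within ~5% (the residual bias comes from fitting the
log of a noisy curve), and the isotropic gyration ratio is unbiased with
a sampling SD of ≈0.05 at 1000 trajectories of 288 frames — so
single-run values of that diagnostic scatter by about ±0.05 even when
everything is correct, which is worth remembering when reading one-off
runs.

### What passing synthetic tests does and does not show

The generator reproduces the *statistical* structure: persistent motion,
fragmented offset Golgi, partial labeling, blinking, background noise.
It does not render optics (no PSF convolution, no photobleaching decay,
no phase channel), does not give cells excluded volume (simulated nuclei
can interpenetrate, which makes long cell–cell contacts somewhat more
frequent than in sparse real cultures), and does not model Golgi shape
change. Passing the end-to-end tests therefore demonstrates the
correctness of the algorithms under controlled conditions — not that any
particular real dataset will segment cleanly, which always depends on the
channel-specific window and sensitivity settings described above.

## Numerical choices and degenerate inputs

* Angles are wrapped to the half-open interval [0°, 180°) (the seam point
  counted once); the shift search uses the integer 1° grid, so mean
  orientations are exact to the grid.
* The truncated-SD calibration is fixed by its two anchors (uniform → 52°,
  degenerate → 0°); samples of fewer than two angles are an error.
* Equal-size clusters in the merger and equal distances in the pairer
  break ties deterministically (row-major first pixel; then ids), so runs
  are reproducible to the byte.
* Constant frames, empty frames, empty candidate tables, single-frame
  trajectories, and all-x ensembles (undefined R_xx/R_yy) each have a
  defined outcome — an empty result or a flagged error naming the cause,
  never silence.
* The linker's branch-and-bound is exact per connected component; at
  sensible densities components hold only a handful of tracks, so exact
  optimisation is affordable.

## Known limitations

Touching nuclei are gated out rather than split, so cells in persistent
contact lose track identity for the duration (the deliberate trade
discussed above); two cells' overlapping Golgi merge into one detection;
pairings are fixed for a whole movie; and linking uses positions only —
a contact between two cells whose trajectories cross can swap identities
without any kinematic signature, which is the main residual error source
in the end-to-end benchmark (pair precision ≈ 0.96, recall ≈ 0.94 at the
default density; the few unrecovered cells are precisely those in long
nucleus–nucleus contacts). These match the failure modes the underlying
method accepts by design.

## A worked example

```{r example, eval = FALSE}
library(ngvtrack)

params <- simulation_params(n_cells = 8, n_frames = 20,
                            frame_shape = c(400, 400),
                            labeled_fraction = 0.6, seed = 5)
truth <- simulate_ground_truth(params)

config <- pipeline_config(out_dir = "ngv_out",
                          golgi_seg = list(sensitivity = 0.025),
                          seed = 5)
res <- run_pipeline(config,
                    nuclei_stack = synthetic_stack(truth, "nuclei"),
                    golgi_stack = synthetic_stack(truth, "golgi"))

res$pairs
res$metrics$orientation_stats
pairing_accuracy(res$pairs, res$nuclei_tracks, res$golgi_tracks, truth)
```

The same stages are scriptable from a shell through
`inst/cli/ngvtrack.R` (`simulate`, `preprocess`, `segment`, `track`,
`pair`, `metrics`, `run`), each a thin wrapper over the functions above.
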