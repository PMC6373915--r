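# ngvtrack

Dual nucleus–Golgi tracking and cell-polarity statistics for two-channel
time-lapse fluorescence microscopy.

## What it is for

When an adherent cell polarizes, its Golgi apparatus repositions relative
to the nucleus before the nucleus itself visibly reorients. Quantifying
that sequence across thousands of cells requires (i) segmenting nuclei
(ellipsoidal, bright) and Golgi bodies (dim, irregular, fragmented) in
every frame, (ii) linking detections into identity-stable trajectories
despite blinking fluorescence, (iii) binding each Golgi to its parent
nucleus, and (iv) turning the result into orientation and motility
statistics. `ngvtrack` implements that chain for researchers studying
directed cell migration and internal polarity on patterned or dynamic
substrates.

## The measurements at its core

* **Nucleus orientation** — the apolar major-axis angle θ ∈ [0°, 180°) of
  a moments-based ellipse fit.
* **Nucleus–Golgi vector (NGV)** — the vector from the nucleus center of
  mass to the paired Golgi centroid; its apolar angle is an internal
  polarity readout that responds to substrate cues earlier than nucleus
  shape.
* **Truncated standard deviation (σ_t)** — the spread of an apolar angle
  sample, minimised over integer re-wrapping shifts and calibrated so a
  uniform sample gives σ_t = 52° and perfect alignment σ_t = 0°; immune
  to the 0°/180° seam.
* **Trajectory anisotropy** — the gyration-tensor diagonal ratio
  R_xx/R_yy (1 = isotropic exploration) and wrinkle-frame speed
  components |v_x|, |v_y|.
* **Persistence** — the velocity autocorrelation function
  C_vv(Δt) = ⟨v̂(t₀)·v̂(t₀+Δt)⟩ and the persistence time −1/slope of its
  semilog decay; plus the mean squared displacement.

Tracking follows the standard cost-minimising frame-linking scheme with a
gap **memory** of 10 frames (an object may vanish for up to 10 frames and
keep its identity), straight-line gap interpolation, and global
best-first nucleus–Golgi pairing by time-averaged distance with conflict
resolution.

A seeded synthetic-movie generator (persistent random walks, rendered
ellipsoidal nuclei, fragmented offset Golgi, 40% labeling, blinking,
background noise — with full ground truth) makes every stage testable
without external data. See `vignettes/methods.Rmd` for the model details
and design decisions.

## A worked example

```r
library(ngvtrack)

params <- simulation_params(n_cells = 8, n_frames = 20,
                            frame_shape = c(400, 400),
                            labeled_fraction = 0.6, seed = 5)
truth <- simulate_ground_truth(params)        # 8 cells, 7 Golgi-labeled

config <- pipeline_config(out_dir = "ngv_out",
                          golgi_seg = list(sensitivity = 0.025), seed = 5)
res <- run_pipeline(config,
                    nuclei_stack = synthetic_stack(truth, "nuclei"),
                    golgi_stack = synthetic_stack(truth, "golgi"))

as.data.frame(res$pairs)
#>   nucleus_id golgi_id mean_distance co_visible_frames
#> 1          6        6       6.94260                20
#> 2          2        3      10.45459                20
#> 3          3        5      12.32333                20
#> 4          5        4      12.74095                20
#> 5          4        2      14.28251                20
#> 6          8        7      14.49788                16
#> 7          7        1      14.91614                18

pairing_accuracy(res$pairs, res$nuclei_tracks, res$golgi_tracks, truth)[1:2]
#> $precision
#> [1] 1
#>
#> $recall
#> [1] 1
```

Each pair row binds one nucleus trajectory to one Golgi trajectory; the
mean distance (px) is the time-averaged centroid separation — here
~7–15 px ≈ 6–12 µm, the expected nucleus–Golgi offset — and all seven
labeled cells are recovered correctly against the generator's ground
truth. `run_pipeline()` also writes `detections.csv`,
`trajectories.csv`, `pairs.csv`, `orientation_stats.csv` (mean
orientation and σ_t per channel and analysis window), `speeds.csv`,
`msd.csv`, `vacf.csv`, `gyration.csv`, `polar_histogram.csv` and
`group_tests.csv` under `out_dir`.

A thin command-line front end over the same functions lives at
`inst/cli/ngvtrack.R` with subcommands `simulate`, `preprocess`,
`segment`, `track`, `pair`, `metrics` and `run`.

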