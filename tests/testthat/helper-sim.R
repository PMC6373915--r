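## Shared fixture builders (all data generated in code at test time).

## Small renderable movie: a handful of cells in a 400x400 px field.
small_movie_params <- function(seed = 5, ...) {
  simulation_params(n_cells = 8, n_frames = 20, frame_shape = c(400, 400),
                    labeled_fraction = 0.6, blink_probability = 0.05,
                    seed = seed, ...)
}

## Open-field parameters for trajectory statistics: domain much larger
## than the exploration length so border reflections are rare.
open_field_params <- function(n_cells, seed, ...) {
  simulation_params(n_cells = n_cells, n_frames = 288,
                    frame_shape = c(8000, 8000), seed = seed, ...)
}

## Analysis configuration matched to the small 400x400 synthetic field
## (clustering cutoff ~14 px, between fragment scatter and cell spacing).
small_movie_config <- function(out_dir = NULL, ...) {
  pipeline_config(out_dir = out_dir, golgi_seg = list(sensitivity = 0.025),
                  ...)
}

## Deterministic pixel blob: n contiguous pixels in a row starting at
## (x0, y0).
pixel_run <- function(n, x0, y0) {
  cbind(x = x0 + seq_len(n) - 1L, y = rep(y0, n))
}
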