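#' Parameters for the synthetic two-channel movie generator
#'
#' Bundles every knob of the synthetic ground-truth generator. Defaults
#' emulate the imaging regime the pipeline was designed for: mouse
#' fibroblasts seeded at 4000 cells/cm^2, imaged every 5 minutes at 10x
#' (0.8 um/px, the scale of an 8 um camera pixel behind a 10x objective),
#' with ~40% of cells carrying a visible Golgi label and frame-to-frame
#' intensity blinking.
#'
#' @param n_cells number of simulated cells (>= 1).
#' @param n_frames number of frames (>= 1).
#' @param frame_interval minutes between frames.
#' @param frame_shape integer c(height, width) of each frame in pixels.
#' @param pixel_size um per pixel.
#' @param persistence_time minutes; exponential decorrelation time of the
#'   heading of the persistent random walk (> 0).
#' @param mean_speed um/min; step speed of each cell.
#' @param anisotropy ratio of x- to y-step scale (1 = isotropic motion).
#' @param nuclei_axes named numeric c(major, minor, jitter) in um: mean full
#'   ellipse axes of nuclei and the SD of their per-cell jitter.
#' @param orientation_concentration axial (von Mises on doubled angles)
#'   concentration of nucleus orientations about the x axis; 0 = uniform
#'   apolar angles.
#' @param ngv_offset named numeric c(mean, jitter) in um: distance from the
#'   nucleus center to the Golgi centroid.
#' @param ngv_concentration axial concentration of nucleus-Golgi vector
#'   angles about the x axis; 0 = uniform.
#' @param golgi_fragments named numeric c(mean, jitter): fragments per Golgi.
#' @param fragment_scatter um; SD of fragment centers about the Golgi
#'   centroid.
#' @param labeled_fraction probability in [0,1] that a cell's Golgi is
#'   fluorescently labeled (visible at all).
#' @param blink_probability per-frame probability in [0,1] that a visible
#'   structure emits no signal.
#' @param blink_max frames; longest permitted dark run (enforced by
#'   construction).
#' @param noise_sigma SD of additive Gaussian background noise (intensity
#'   units).
#' @param background mean background intensity.
#' @param nucleus_amp peak nucleus intensity above background.
#' @param golgi_amp peak Golgi fragment intensity above background.
#' @param seed integer seed; identical parameters and seed give bit-identical
#'   ground truth and pixel data.
#' @return an object of class `simulation_params` (a validated list).
#' @export
simulation_params <- function(n_cells = 100,
                              n_frames = 288,
                              frame_interval = 5,
                              frame_shape = c(1976L, 1976L),
                              pixel_size = 0.8,
                              persistence_time = 240,
                              mean_speed = 0.5,
                              anisotropy = 1,
                              nuclei_axes = c(major = 18, minor = 9, jitter = 1.5),
                              orientation_concentration = 0,
                              ngv_offset = c(mean = 10, jitter = 2),
                              ngv_concentration = 0,
                              golgi_fragments = c(mean = 4, jitter = 1),
                              fragment_scatter = 3,
                              labeled_fraction = 0.4,
                              blink_probability = 0.1,
                              blink_max = 10,
                              noise_sigma = 50,
                              background = 100,
                              nucleus_amp = 4000,
                              golgi_amp = 3000,
                              seed = 1L) {
  p <- list(n_cells = as.integer(n_cells), n_frames = as.integer(n_frames),
            frame_interval = frame_interval, frame_shape = as.integer(frame_shape),
            pixel_size = pixel_size, persistence_time = persistence_time,
            mean_speed = mean_speed, anisotropy = anisotropy,
            nuclei_axes = nuclei_axes,
            orientation_concentration = orientation_concentration,
            ngv_offset = ngv_offset, ngv_concentration = ngv_concentration,
            golgi_fragments = golgi_fragments, fragment_scatter = fragment_scatter,
            labeled_fraction = labeled_fraction,
            blink_probability = blink_probability, blink_max = as.integer(blink_max),
            noise_sigma = noise_sigma, background = background,
            nucleus_amp = nucleus_amp, golgi_amp = golgi_amp,
            seed = as.integer(seed))
  validate_simulation_params(p)
  class(p) <- "simulation_params"
  p
}

validate_simulation_params <- function(p) {
  stopifnot(p$n_cells >= 1, p$n_frames >= 1, length(p$frame_shape) == 2,
            all(p$frame_shape >= 1), p$pixel_size > 0, p$frame_interval > 0)
  if (!is.finite(p$persistence_time) || p$persistence_time <= 0)
    stop("persistence_time must be > 0")
  if (p$mean_speed < 0) stop("mean_speed must be >= 0")
  if (p$anisotropy <= 0) stop("anisotropy must be > 0")
  if (p$orientation_concentration < 0 || p$ngv_concentration < 0)
    stop("concentration parameters must be >= 0")
  for (nm in c("labeled_fraction", "blink_probability")) {
    v <- p[[nm]]
    if (v < 0 || v > 1) stop(nm, " must be in [0, 1]")
  }
  stopifnot(p$blink_max >= 0, p$noise_sigma >= 0,
            p$golgi_fragments[["mean"]] >= 1,
            p$nuclei_axes[["major"]] >= p$nuclei_axes[["minor"]],
            p$nuclei_axes[["minor"]] > 0)
  invisible(p)
}

#' @export
print.simulation_params <- function(x, ...) {
  cat("Synthetic movie parameters\n")
  cat(sprintf("  %d cells, %d frames @ %g min, %dx%d px @ %g um/px\n",
              x$n_cells, x$n_frames, x$frame_interval,
              x$frame_shape[1], x$frame_shape[2], x$pixel_size))
  cat(sprintf("  motion: speed %g um/min, persistence %g min, anisotropy %g\n",
              x$mean_speed, x$persistence_time, x$anisotropy))
  cat(sprintf("  labeling: %g labeled, blink p=%g (max run %d), seed %d\n",
              x$labeled_fraction, x$blink_probability, x$blink_max, x$seed))
  invisible(x)
}

#' Brightness/contrast adjustment parameters
#'
#' The per-frame intensity window is set `n_low` standard deviations below
#' and `n_high` above the mean of a Gaussian fitted to the pixel-intensity
#' histogram. The defaults are display-normalisation values; channels with a
#' large signal-to-background ratio need a larger `n_high` so that signal
#' does not saturate together with the background tail (see the methods
#' vignette).
#'
#' @param n_low,n_high dimensionless multiples of the fitted background SD.
#' @return an `adjust_params` list.
#' @export
adjust_params <- function(n_low = 1, n_high = 3) {
  structure(list(n_low = n_low, n_high = n_high), class = "adjust_params")
}

#' Golgi segmentation parameters
#'
#' @param hard_cutoff intensity threshold separating Golgi signal from
#'   background on the contrast-adjusted frame.
#' @param sensitivity dimensionless in (0,1); the single-linkage clustering
#'   cutoff is `sensitivity` times the frame diagonal. The published default
#'   is deliberately over-sensitive (fragments split rather than merged);
#'   the merge stage reassembles them.
#' @param min_cluster_px clusters with fewer pixels are discarded.
#' @param merge_distance px; clusters whose convex hulls approach within
#'   this distance are absorbed into the same Golgi body. Choose it between
#'   the fragment scatter and the typical inter-cell spacing.
#' @return a `golgi_seg_params` list.
#' @export
golgi_seg_params <- function(hard_cutoff = 30000, sensitivity = 0.1,
                             min_cluster_px = 3L, merge_distance = 25) {
  if (sensitivity <= 0 || sensitivity >= 1) stop("sensitivity must be in (0, 1)")
  if (min_cluster_px < 1) stop("min_cluster_px must be >= 1")
  if (merge_distance <= 0) stop("merge_distance must be > 0")
  structure(list(hard_cutoff = hard_cutoff, sensitivity = sensitivity,
                 min_cluster_px = as.integer(min_cluster_px),
                 merge_distance = merge_distance),
            class = "golgi_seg_params")
}

#' Trajectory linking parameters
#'
#' @param max_displacement px; the largest frame-to-frame displacement a
#'   single link may span.
#' @param memory frames; how long an undetected object remains eligible for
#'   re-linking before its identity is retired. Default 10, the validated
#'   value for 5-minute fibroblast movies.
#' @return a `link_params` list.
#' @export
link_params <- function(max_displacement = 15, memory = 10L) {
  if (max_displacement <= 0) stop("max_displacement must be > 0")
  if (memory < 0) stop("memory must be >= 0")
  structure(list(max_displacement = max_displacement, memory = as.integer(memory)),
            class = "link_params")
}

#' Nucleus-Golgi pairing parameters
#'
#' @param max_pair_distance px; pairings whose time-averaged
#'   nucleus-to-Golgi distance exceeds this cutoff are excluded.
#' @return a `pair_params` list.
#' @export
pair_params <- function(max_pair_distance = 40) {
  if (max_pair_distance <= 0) stop("max_pair_distance must be > 0")
  structure(list(max_pair_distance = max_pair_distance), class = "pair_params")
}
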