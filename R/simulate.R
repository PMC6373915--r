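#' Simulate persistent random-walk cell trajectories
#'
#' Each cell performs a heading-persistent random walk: the heading angle
#' diffuses so that its direction decorrelates exponentially with time
#' constant `persistence_time`, which makes the ensemble velocity
#' autocorrelation an exponential with that decay time. Steps have fixed
#' length `mean_speed * frame_interval`; x-displacements are scaled by
#' `anisotropy`; positions are reflected at the frame borders.
#'
#' @param params a [simulation_params()] object.
#' @return a list of class `ngv_paths` with `x` and `y` matrices
#'   (`n_frames` rows by `n_cells` columns, um) and the parameters.
#' @export
simulate_trajectories <- function(params) {
  validate_simulation_params(params)
  set.seed(params$seed)
  sim_paths(params)
}

sim_paths <- function(params) {
  n <- params$n_cells; tt <- params$n_frames
  dt <- params$frame_interval
  lim <- c(params$frame_shape[2], params$frame_shape[1]) * params$pixel_size
  sd_theta <- sqrt(2 * dt / params$persistence_time)
  theta0 <- stats::runif(n, 0, 2 * pi)
  col_cumsum <- function(m) {
    cs <- apply(m, 2, cumsum)
    if (!is.matrix(cs)) cs <- matrix(cs, nrow = 1)
    cs
  }
  if (tt > 1) {
    dth <- matrix(stats::rnorm((tt - 1) * n, 0, sd_theta), tt - 1, n)
    theta <- rbind(theta0, sweep(col_cumsum(dth), 2, theta0, "+"))
  } else {
    theta <- matrix(theta0, 1, n)
  }
  step <- params$mean_speed * dt
  x0 <- stats::runif(n, 0, lim[1])
  y0 <- stats::runif(n, 0, lim[2])
  if (tt > 1) {
    dx <- params$anisotropy * step * cos(theta[-tt, , drop = FALSE])
    dy <- step * sin(theta[-tt, , drop = FALSE])
    x <- rbind(x0, sweep(col_cumsum(dx), 2, x0, "+"))
    y <- rbind(y0, sweep(col_cumsum(dy), 2, y0, "+"))
  } else {
    x <- matrix(x0, 1, n); y <- matrix(y0, 1, n)
  }
  dimnames(x) <- dimnames(y) <- NULL
  structure(list(x = reflect_into(x, lim[1]), y = reflect_into(y, lim[2]),
                 params = params),
            class = "ngv_paths")
}

## Fold an unconstrained coordinate into [0, lim] (reflecting boundaries).
reflect_into <- function(v, lim) {
  v <- v %% (2 * lim)
  ifelse(v > lim, 2 * lim - v, v)
}

#' Simulate per-cell apolar orientation angles
#'
#' Nucleus orientations are drawn from an axial von Mises family (von Mises
#' on doubled angles) about the x axis; `orientation_concentration = 0`
#' gives the uniform apolar distribution on [0, 180). Orientations are held
#' fixed over time for each cell: the generator emulates the alignment
#' statistics of a population, not in-place nuclear rotation.
#'
#' @param params a [simulation_params()] object.
#' @return numeric vector of `n_cells` angles in degrees, [0, 180).
#' @export
simulate_orientations <- function(params) {
  validate_simulation_params(params)
  set.seed(params$seed)
  sample_axial_angles(params$n_cells, params$orientation_concentration)
}

#' Place Golgi bodies relative to simulated nuclei
#'
#' For each labeled cell the Golgi centroid sits `ngv_offset` um from the
#' nucleus center along an angle drawn with axial concentration
#' `ngv_concentration` about the x axis (either sense of the axis with
#' equal probability); fragments are scattered around the centroid with SD
#' `fragment_scatter` and ride rigidly with the nucleus. Unlabeled cells
#' get no Golgi, emulating partial transfection.
#'
#' @param paths an `ngv_paths` object from [simulate_trajectories()].
#' @param params a [simulation_params()] object.
#' @return a list with `labeled` (logical per cell), `golgi_x`/`golgi_y`
#'   centroid matrices (um; NA for unlabeled cells), `fragments` (per-cell
#'   matrix of fragment offsets about the centroid, um) and `pairs`
#'   (nucleus id to golgi id table over labeled cells).
#' @export
place_golgi <- function(paths, params) {
  set.seed(params$seed + 1L)
  sim_golgi(paths, params)
}

sim_golgi <- function(paths, params) {
  n <- params$n_cells
  labeled <- stats::runif(n) < params$labeled_fraction
  axial <- sample_axial_angles(n, params$ngv_concentration)
  flip <- stats::runif(n) < 0.5
  phi <- (axial + ifelse(flip, 180, 0)) * pi / 180
  off <- params$ngv_offset[["mean"]] +
    stats::rnorm(n, 0, params$ngv_offset[["jitter"]])
  off <- pmax(off, 0.1)
  nf <- pmax(1L, as.integer(round(
    params$golgi_fragments[["mean"]] +
      stats::rnorm(n, 0, params$golgi_fragments[["jitter"]]))))
  fragments <- vector("list", n)
  gx <- gy <- matrix(NA_real_, nrow(paths$x), n)
  for (i in seq_len(n)) {
    if (!labeled[i]) next
    fr <- cbind(stats::rnorm(nf[i], 0, params$fragment_scatter),
                stats::rnorm(nf[i], 0, params$fragment_scatter))
    ## centroid is the mean of the rendered fragments, so recenter the
    ## scatter: the stored centroid is exactly what segmentation recovers
    fr <- sweep(fr, 2, colMeans(fr))
    fragments[[i]] <- fr
    gx[, i] <- paths$x[, i] + off[i] * cos(phi[i])
    gy[, i] <- paths$y[, i] + off[i] * sin(phi[i])
  }
  list(labeled = labeled, golgi_x = gx, golgi_y = gy, fragments = fragments,
       ngv_angle = wrap_apolar(phi * 180 / pi), ngv_offset = off,
       pairs = data.frame(nucleus_id = which(labeled),
                          golgi_id = which(labeled)))
}

## i.i.d. per-frame blinking with dark runs capped at blink_max: any frame
## that would extend a dark run beyond the cap is forced visible.
sim_visibility <- function(tt, n, p, blink_max) {
  vis <- matrix(stats::runif(tt * n) >= p, tt, n)
  if (blink_max < 1) {
    vis[] <- TRUE
    return(vis)
  }
  run <- integer(n)
  for (f in seq_len(tt)) {
    run <- ifelse(vis[f, ], 0L, run + 1L)
    force_on <- run > blink_max
    if (any(force_on)) {
      vis[f, force_on] <- TRUE
      run[force_on] <- 0L
    }
  }
  vis
}

#' Generate full ground truth for a synthetic two-channel movie
#'
#' Composes trajectory simulation, orientation sampling, Golgi placement,
#' per-cell nucleus geometry and per-frame blinking under one seed. The
#' result carries everything the renderer and the evaluation helpers need:
#' positions, ellipse parameters, fragment offsets, visibility flags and
#' the nucleus-to-Golgi pairing table.
#'
#' @param params a [simulation_params()] object.
#' @return an object of class `ngv_truth`.
#' @export
simulate_ground_truth <- function(params) {
  validate_simulation_params(params)
  set.seed(params$seed)
  paths <- sim_paths(params)
  angle <- sample_axial_angles(params$n_cells, params$orientation_concentration)
  ax <- params$nuclei_axes
  major <- pmax(ax[["major"]] + stats::rnorm(params$n_cells, 0, ax[["jitter"]]), 2)
  minor <- pmax(ax[["minor"]] + stats::rnorm(params$n_cells, 0, ax[["jitter"]]), 1)
  swap <- minor > major
  if (any(swap)) {
    tmp <- major[swap]; major[swap] <- minor[swap]; minor[swap] <- tmp
  }
  golgi <- sim_golgi(paths, params)
  tt <- params$n_frames
  nuc_vis <- sim_visibility(tt, params$n_cells, params$blink_probability,
                            params$blink_max)
  gol_vis <- sim_visibility(tt, params$n_cells, params$blink_probability,
                            params$blink_max)
  gol_vis[, !golgi$labeled] <- FALSE
  structure(list(params = params,
                 x = paths$x, y = paths$y,
                 angle = angle, major = major, minor = minor,
                 labeled = golgi$labeled,
                 golgi_x = golgi$golgi_x, golgi_y = golgi$golgi_y,
                 fragments = golgi$fragments,
                 ngv_angle = golgi$ngv_angle,
                 nuc_visible = nuc_vis, golgi_visible = gol_vis,
                 pairs = golgi$pairs),
            class = "ngv_truth")
}

#' @export
print.ngv_truth <- function(x, ...) {
  cat(sprintf("Synthetic ground truth: %d cells (%d Golgi-labeled), %d frames\n",
              x$params$n_cells, sum(x$labeled), x$params$n_frames))
  invisible(x)
}

#' Ground truth as a long per-frame table
#'
#' @param truth an `ngv_truth` object.
#' @return data.frame with columns `frame` (0-based), `cell_id`, `channel`
#'   ("nuclei" or "golgi"), `x_px`, `y_px`, `angle_deg` (nuclei only) and
#'   `visible`.
#' @export
ground_truth_table <- function(truth) {
  p <- truth$params
  tt <- p$n_frames; n <- p$n_cells
  frame <- rep(0:(tt - 1), n)
  cell <- rep(seq_len(n), each = tt)
  nuc <- data.frame(frame = frame, cell_id = cell, channel = "nuclei",
                    x_px = as.vector(truth$x) / p$pixel_size,
                    y_px = as.vector(truth$y) / p$pixel_size,
                    angle_deg = rep(truth$angle, each = tt),
                    visible = as.vector(truth$nuc_visible))
  lab <- truth$labeled[cell]
  gol <- data.frame(frame = frame[lab], cell_id = cell[lab], channel = "golgi",
                    x_px = as.vector(truth$golgi_x)[lab] / p$pixel_size,
                    y_px = as.vector(truth$golgi_y)[lab] / p$pixel_size,
                    angle_deg = NA_real_,
                    visible = as.vector(truth$golgi_visible)[lab])
  rbind(nuc, gol)
}

## ---- rendering ------------------------------------------------------------

GOLGI_BLOB_SIGMA_PX <- 1.5  # rendered fragment width

#' Render one frame of a synthetic movie
#'
#' Nuclei are filled anti-aliased ellipses with a Gaussian interior
#' falloff; Golgi fragments are small Gaussian blobs. Additive Gaussian
#' background noise with `noise_sigma` is seeded per frame and channel so
#' frames can be rendered in any order and remain bit-reproducible.
#'
#' @param truth an `ngv_truth` object.
#' @param frame 1-based frame number.
#' @param channel "nuclei" or "golgi".
#' @return numeric matrix (height x width), intensities clipped to
#'   [0, 65535].
#' @export
render_frame <- function(truth, frame, channel = c("nuclei", "golgi")) {
  channel <- match.arg(channel)
  p <- truth$params
  h <- p$frame_shape[1]; w <- p$frame_shape[2]
  too_big <- which(truth$major / p$pixel_size + 4 > min(h, w))
  if (length(too_big))
    stop("frame too small for cell ", too_big[1],
         " (nucleus major axis ", round(truth$major[too_big[1]], 1), " um)")
  ## patches are applied in this frame so the (large) image is modified in
  ## place rather than copied per object
  img <- matrix(0, h, w)
  if (channel == "nuclei") {
    for (i in seq_len(p$n_cells)) {
      if (!truth$nuc_visible[frame, i]) next
      pt <- ellipse_patch(h, w,
                          cx = truth$x[frame, i] / p$pixel_size,
                          cy = truth$y[frame, i] / p$pixel_size,
                          a = truth$major[i] / (2 * p$pixel_size),
                          b = truth$minor[i] / (2 * p$pixel_size),
                          theta = truth$angle[i] * pi / 180,
                          amp = p$nucleus_amp)
      if (!is.null(pt))
        img[pt$rows, pt$cols] <- img[pt$rows, pt$cols] + pt$patch
    }
  } else {
    for (i in seq_len(p$n_cells)) {
      if (!truth$golgi_visible[frame, i]) next
      fr <- truth$fragments[[i]]
      for (k in seq_len(nrow(fr))) {
        pt <- blob_patch(h, w,
                         cx = (truth$golgi_x[frame, i] + fr[k, 1]) / p$pixel_size,
                         cy = (truth$golgi_y[frame, i] + fr[k, 2]) / p$pixel_size,
                         sigma = GOLGI_BLOB_SIGMA_PX,
                         amp = p$golgi_amp)
        if (!is.null(pt))
          img[pt$rows, pt$cols] <- img[pt$rows, pt$cols] + pt$patch
      }
    }
  }
  noise_seed <- (p$seed * 1009 + 2 * frame + (channel == "golgi")) %% .Machine$integer.max
  set.seed(noise_seed)
  img <- img + (p$background + stats::rnorm(h * w, 0, p$noise_sigma))
  img[img < 0] <- 0
  img[img > 65535] <- 65535
  img
}

## Patch of an anti-aliased filled ellipse (semi-axes a, b px at angle
## theta) with a mild Gaussian interior falloff; 0-based center. NULL when
## fully outside the frame.
ellipse_patch <- function(h, w, cx, cy, a, b, theta, amp) {
  e <- ceiling(a + 2)
  r0 <- max(1, floor(cy + 1 - e)); r1 <- min(h, ceiling(cy + 1 + e))
  c0 <- max(1, floor(cx + 1 - e)); c1 <- min(w, ceiling(cx + 1 + e))
  if (r1 < r0 || c1 < c0) return(NULL)
  rows <- r0:r1; cols <- c0:c1
  dy <- (rows - 1) - cy
  dx <- (cols - 1) - cx
  ct <- cos(theta); st <- sin(theta)
  xr <- outer(dy * st, dx * ct, "+")   # rows x cols: dx*ct + dy*st
  yr <- outer(dy * ct, -dx * st, "+")  # -dx*st + dy*ct
  q <- sqrt((xr / a)^2 + (yr / b)^2)
  cov <- pmin(1, pmax(0, (1 - q) * b + 0.5))       # ~1 px anti-aliased edge
  list(rows = rows, cols = cols,
       patch = amp * (0.55 + 0.45 * exp(-1.5 * q^2)) * cov)
}

blob_patch <- function(h, w, cx, cy, sigma, amp) {
  e <- ceiling(4 * sigma)
  r0 <- max(1, floor(cy + 1 - e)); r1 <- min(h, ceiling(cy + 1 + e))
  c0 <- max(1, floor(cx + 1 - e)); c1 <- min(w, ceiling(cx + 1 + e))
  if (r1 < r0 || c1 < c0) return(NULL)
  rows <- r0:r1; cols <- c0:c1
  dy2 <- ((rows - 1) - cy)^2
  dx2 <- ((cols - 1) - cx)^2
  r2 <- outer(dy2, dx2, "+")
  list(rows = rows, cols = cols, patch = amp * exp(-r2 / (2 * sigma^2)))
}

#' Lazy rendered stack for one channel of a synthetic movie
#'
#' @param truth an `ngv_truth` object.
#' @param channel "nuclei" or "golgi".
#' @return an `ngv_stack` whose frames are rendered on access.
#' @export
synthetic_stack <- function(truth, channel = c("nuclei", "golgi")) {
  channel <- match.arg(channel)
  new_stack(truth$params$n_frames, truth$params$frame_shape,
            function(i) render_frame(truth, i, channel),
            source = paste0("synthetic-", channel))
}

#' Render a whole synthetic movie
#'
#' @param truth an `ngv_truth` object.
#' @param out_dir optional directory; when given, writes `nuclei.tif` and
#'   `golgi.tif` (16-bit multi-page TIFF), `ground_truth.csv` and
#'   `pairs_truth.csv` there.
#' @return invisibly, a list with the two (lazy) stacks and the paths
#'   written (if any).
#' @export
render_movie <- function(truth, out_dir = NULL) {
  stacks <- list(nuclei = synthetic_stack(truth, "nuclei"),
                 golgi = synthetic_stack(truth, "golgi"))
  paths <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (ch in names(stacks)) {
      f <- file.path(out_dir, paste0(ch, ".tif"))
      write_stack(stacks[[ch]], f, bits = 16)
      paths <- c(paths, f)
    }
    gt <- file.path(out_dir, "ground_truth.csv")
    utils::write.csv(ground_truth_table(truth), gt, row.names = FALSE)
    pr <- file.path(out_dir, "pairs_truth.csv")
    utils::write.csv(truth$pairs, pr, row.names = FALSE)
    paths <- c(paths, gt, pr)
  }
  invisible(list(stacks = stacks, paths = paths))
}

#' Convert path matrices to a list of per-cell trajectories
#'
#' @param paths an `ngv_paths` object (or any list with `x`, `y` matrices,
#'   frames in rows and cells in columns).
#' @return list of data.frames with columns `frame` (0-based), `x`, `y`,
#'   `interpolated` (all FALSE), suitable for the metrics functions.
#' @export
as_trajectories <- function(paths) {
  tt <- nrow(paths$x)
  lapply(seq_len(ncol(paths$x)), function(i) {
    data.frame(frame = 0:(tt - 1), x = paths$x[, i], y = paths$y[, i],
               interpolated = FALSE)
  })
}
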