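#' Rotate positions into the wrinkle frame
#'
#' Trajectory statistics are reported in a coordinate system whose +x axis
#' lies along the substrate wrinkles. This applies the rigid rotation that
#' maps the wrinkle direction (given as an angle from the image x axis, in
#' degrees) onto +x.
#'
#' @param positions two-column matrix or data.frame of (x, y).
#' @param wrinkle_angle degrees; 0 leaves the data untouched.
#' @return matrix of rotated (x, y).
#' @export
rotate_to_wrinkle_frame <- function(positions, wrinkle_angle) {
  m <- as.matrix(positions)[, 1:2, drop = FALSE]
  a <- wrinkle_angle * pi / 180
  cbind(x = m[, 1] * cos(a) + m[, 2] * sin(a),
        y = -m[, 1] * sin(a) + m[, 2] * cos(a))
}

#' Nucleus-Golgi vector angles for a paired cell
#'
#' The NGV is the vector from the nucleus center of mass to the Golgi
#' centroid; its apolar angle against the x axis is the internal-polarity
#' readout. Frames where either member has no position give no value.
#'
#' @param nucleus_traj,golgi_traj trajectory data.frames (columns `frame`,
#'   `x`, `y`), e.g. from [fill_gaps()].
#' @return data.frame with `frame` and `angle` (degrees in [0, 180)) over
#'   the co-visible frames.
#' @export
ngv_angle <- function(nucleus_traj, golgi_traj) {
  common <- intersect(nucleus_traj$frame, golgi_traj$frame)
  if (!length(common))
    return(data.frame(frame = integer(0), angle = numeric(0)))
  ni <- match(common, nucleus_traj$frame)
  gi <- match(common, golgi_traj$frame)
  dx <- golgi_traj$x[gi] - nucleus_traj$x[ni]
  dy <- golgi_traj$y[gi] - nucleus_traj$y[ni]
  keep <- dx != 0 | dy != 0
  data.frame(frame = common[keep],
             angle = wrap_apolar(atan2(dy[keep], dx[keep]) * 180 / pi))
}

#' Per-frame speed and velocity components of a trajectory
#'
#' Speeds come from frame-to-frame center-of-mass displacements of the
#' (gap-filled) trajectory; the absolute x and y velocity components are
#' reported in the wrinkle frame, where x lies along the wrinkles.
#'
#' @param traj trajectory data.frame (`frame`, `x`, `y`), positions in px.
#' @param pixel_size um per px.
#' @param frame_interval minutes per frame.
#' @return an object of class `speed_series`: data.frame with `frame`,
#'   `speed`, `abs_vx`, `abs_vy` (um/min), plus attribute `vx_vy_ratio`
#'   (mean |vx| / mean |vy|; NA when the trajectory never moves in y).
#' @export
compute_speed <- function(traj, pixel_size = 1, frame_interval = 5) {
  n <- nrow(traj)
  if (n < 2) {
    out <- data.frame(frame = integer(0), speed = numeric(0),
                      abs_vx = numeric(0), abs_vy = numeric(0))
    attr(out, "vx_vy_ratio") <- NA_real_
    class(out) <- c("speed_series", "data.frame")
    return(out)
  }
  dt <- diff(traj$frame) * frame_interval
  vx <- diff(traj$x) * pixel_size / dt
  vy <- diff(traj$y) * pixel_size / dt
  out <- data.frame(frame = traj$frame[-1], speed = sqrt(vx^2 + vy^2),
                    abs_vx = abs(vx), abs_vy = abs(vy))
  mvy <- mean(out$abs_vy)
  attr(out, "vx_vy_ratio") <- if (mvy == 0) NA_real_ else mean(out$abs_vx) / mvy
  class(out) <- c("speed_series", "data.frame")
  out
}

#' Ensemble- and time-averaged mean squared displacement
#'
#' @param trajectories list of trajectory data.frames (`frame`, `x`, `y`).
#' @param frame_interval minutes per frame.
#' @param max_lag largest lag in minutes (default: full span).
#' @return data.frame with `lag` (minutes) and `msd` (squared position
#'   units), averaged over all trajectories and start times.
#' @export
msd <- function(trajectories, frame_interval = 5, max_lag = NULL) {
  if (!length(trajectories)) stop("msd needs at least one trajectory")
  mats <- traj_matrices(trajectories)
  tt <- ncol(mats$x)
  max_fr <- if (is.null(max_lag)) tt - 1 else
    min(tt - 1, floor(max_lag / frame_interval))
  lags <- seq_len(max_fr)
  out <- vapply(lags, function(l) {
    dx <- mats$x[, (1 + l):tt, drop = FALSE] - mats$x[, 1:(tt - l), drop = FALSE]
    dy <- mats$y[, (1 + l):tt, drop = FALSE] - mats$y[, 1:(tt - l), drop = FALSE]
    mean(dx^2 + dy^2, na.rm = TRUE)
  }, numeric(1))
  data.frame(lag = lags * frame_interval, msd = out)
}

#' Gyration-tensor anisotropy of an ensemble of trajectories
#'
#' For every trajectory the diagonal elements of the radius-of-gyration
#' tensor, R_xx and R_yy, are the time-variances of the x and y coordinate
#' about the trajectory mean; they quantify how far the cell explores along
#' and perpendicular to the wrinkle axis. The ensemble summary averages
#' each element over trajectories and reports the ratio of those means:
#' values near 1 mean isotropic exploration, above 1 preferential travel
#' along x.
#'
#' @param trajectories list of trajectory data.frames (`frame`, `x`, `y`),
#'   each with at least 2 frames.
#' @return an object of class `gyration_tensor`: list with `r_xx`, `r_yy`
#'   (ensemble means), `ratio`, and the per-trajectory table.
#' @export
gyration_ratio <- function(trajectories) {
  if (!length(trajectories)) stop("gyration_ratio needs trajectories")
  per <- t(vapply(trajectories, function(tr) {
    if (nrow(tr) < 2) stop("each trajectory needs at least 2 frames")
    c(r_xx = mean((tr$x - mean(tr$x))^2),
      r_yy = mean((tr$y - mean(tr$y))^2))
  }, numeric(2)))
  r_xx <- mean(per[, "r_xx"]); r_yy <- mean(per[, "r_yy"])
  if (r_yy == 0)
    stop("gyration ratio undefined: no trajectory explores the y direction")
  structure(list(r_xx = r_xx, r_yy = r_yy, ratio = r_xx / r_yy,
                 per_trajectory = as.data.frame(per)),
            class = "gyration_tensor")
}

#' @export
print.gyration_tensor <- function(x, ...) {
  cat(sprintf("Gyration tensor over %d trajectories: R_xx = %.3g, R_yy = %.3g, ratio = %.3f\n",
              nrow(x$per_trajectory), x$r_xx, x$r_yy, x$ratio))
  invisible(x)
}

#' Velocity autocorrelation function of an ensemble of trajectories
#'
#' Velocities are the instantaneous displacements between sequential
#' frames, normalised to unit vectors; C_vv(dt) averages their dot product
#' over all trajectories and start times. Zero-length displacements carry
#' no direction and are skipped. The curve is conventionally examined only
#' up to a cutoff lag (default 600 minutes = 10 h) beyond which the signal
#' to noise is poor.
#'
#' @param trajectories list of trajectory data.frames (`frame`, `x`, `y`).
#' @param frame_interval minutes per frame.
#' @param max_lag minutes; largest lag evaluated.
#' @return an object of class `vacf_curve`: data.frame with `lag` (minutes)
#'   and `vacf` in [-1, 1]; `vacf` at lag 0 is 1 by construction.
#' @export
vacf <- function(trajectories, frame_interval = 5, max_lag = 600) {
  mats <- traj_matrices(trajectories)
  tt <- ncol(mats$x)
  dx <- mats$x[, -1, drop = FALSE] - mats$x[, -tt, drop = FALSE]
  dy <- mats$y[, -1, drop = FALSE] - mats$y[, -tt, drop = FALSE]
  len <- sqrt(dx^2 + dy^2)
  len[len == 0] <- NA                      # zero step: direction undefined
  ux <- dx / len; uy <- dy / len
  nv <- ncol(ux)
  max_fr <- min(nv - 1, floor(max_lag / frame_interval))
  lags <- 0:max_fr
  vals <- vapply(lags, function(l) {
    if (l == 0) return(1)
    a <- 1:(nv - l); b <- (1 + l):nv
    mean(ux[, a, drop = FALSE] * ux[, b, drop = FALSE] +
           uy[, a, drop = FALSE] * uy[, b, drop = FALSE], na.rm = TRUE)
  }, numeric(1))
  structure(data.frame(lag = lags * frame_interval, vacf = vals),
            class = c("vacf_curve", "data.frame"))
}

#' Persistence time from the semilog decay of a VACF
#'
#' Fits a least-squares line to log C_vv versus lag over the positive
#' values of the curve; the persistence time is -1/slope. A flat or rising
#' curve has no decay and is flagged with NA.
#'
#' @param curve a `vacf_curve` (or data.frame with `lag` and `vacf`).
#' @param max_lag minutes; restrict the fit to lags up to this value.
#' @return list with `persistence_time` (minutes, NA if non-decaying),
#'   `slope` and `n_points`.
#' @export
fit_persistence <- function(curve, max_lag = 600) {
  sel <- curve$vacf > 0 & curve$lag <= max_lag
  if (sum(sel) < 3)
    stop("persistence fit needs at least 3 positive VACF values")
  fit <- stats::lm(log(vacf) ~ lag, data = curve[sel, ])
  slope <- unname(stats::coef(fit)[2])
  list(persistence_time = if (is.na(slope) || slope >= 0) NA_real_ else -1 / slope,
       slope = slope, n_points = sum(sel))
}

#' Nonparametric group comparison with Bonferroni-corrected post hocs
#'
#' Omnibus Kruskal-Wallis test across groups followed by pairwise Wilcoxon
#' rank-sum tests whose p-values are Bonferroni-multiplied (capped at 1).
#' Significance is flagged at 0.05 (*) and 0.01 (**).
#'
#' @param samples_by_group named list of numeric vectors, each of length
#'   >= 2.
#' @return list with `kruskal` (htest), `pairwise` (data.frame of group
#'   pairs, adjusted p-values and significance marks) and `n_comparisons`.
#' @export
compare_groups <- function(samples_by_group) {
  if (length(samples_by_group) < 2)
    stop("compare_groups needs at least 2 groups")
  sizes <- vapply(samples_by_group, length, integer(1))
  if (any(sizes < 2)) stop("every group needs at least 2 values")
  if (is.null(names(samples_by_group)))
    names(samples_by_group) <- paste0("group", seq_along(samples_by_group))
  values <- unlist(samples_by_group, use.names = FALSE)
  groups <- factor(rep(names(samples_by_group), sizes),
                   levels = names(samples_by_group))
  kw <- stats::kruskal.test(values, groups)
  combs <- utils::combn(levels(groups), 2)
  m <- ncol(combs)
  pw <- apply(combs, 2, function(pair) {
    p <- suppressWarnings(stats::wilcox.test(
      samples_by_group[[pair[1]]], samples_by_group[[pair[2]]])$p.value)
    min(1, p * m)
  })
  marks <- ifelse(pw < 0.01, "**", ifelse(pw < 0.05, "*", ""))
  list(kruskal = kw,
       pairwise = data.frame(group1 = combs[1, ], group2 = combs[2, ],
                             p_adjusted = pw, significance = marks),
       n_comparisons = m)
}

## Stack trajectories into cells x frames matrices aligned on frame index
## (NA where a trajectory has no position).
traj_matrices <- function(trajectories) {
  if (!length(trajectories)) stop("no trajectories")
  all_frames <- sort(unique(unlist(lapply(trajectories, `[[`, "frame"))))
  nt <- length(trajectories)
  x <- y <- matrix(NA_real_, nt, length(all_frames))
  for (i in seq_len(nt)) {
    tr <- trajectories[[i]]
    j <- match(tr$frame, all_frames)
    x[i, j] <- tr$x
    y[i, j] <- tr$y
  }
  list(x = x, y = y, frames = all_frames)
}
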