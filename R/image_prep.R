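#' Fit a Gaussian to a frame's pixel-intensity distribution
#'
#' Live-cell movies drift in brightness (photobleaching, lamp fluctuation),
#' so each frame is normalised from its own intensity statistics. The pixel
#' intensities are binned into a histogram and a Gaussian is least-squares
#' fitted to it; because background dominates the pixel count, the fit
#' locks onto the background mode even in the presence of bright objects.
#' If the fit fails to converge the sample mean and SD are used instead and
#' the result is flagged.
#'
#' @param frame numeric matrix of intensities.
#' @param bins number of histogram bins over the observed range.
#' @param max_pixels cap on the number of pixels binned; larger frames are
#'   subsampled with a regular stride (deterministic, statistically
#'   equivalent for a background fit).
#' @return list of class `intensity_fit` with `mean`, `sigma`, `amplitude`,
#'   `converged`.
#' @export
fit_intensity_distribution <- function(frame, bins = 256, max_pixels = 500000) {
  v <- as.numeric(frame)
  if (!length(v)) stop("frame is empty")
  if (length(v) > max_pixels)
    v <- v[seq(1, length(v), by = ceiling(length(v) / max_pixels))]
  rng <- range(v)
  if (rng[1] == rng[2]) {
    return(structure(list(mean = rng[1], sigma = 1, amplitude = length(v),
                          converged = FALSE),
                     class = "intensity_fit"))
  }
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  h <- hist(v, breaks = breaks, plot = FALSE)
  counts <- h$counts
  mids <- h$mids
  mode_i <- which.max(counts)
  ## half-max width around the mode as a robust width start
  half <- counts >= counts[mode_i] / 2
  s0 <- max(diff(range(mids[half])) / 2.355, diff(mids)[1])
  fit <- tryCatch({
    f <- minpack.lm::nlsLM(
      counts ~ A * exp(-(mids - mu)^2 / (2 * s^2)),
      start = list(A = counts[mode_i], mu = mids[mode_i], s = s0),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    co <- stats::coef(f)
    if (!is.finite(co[["s"]]) || abs(co[["s"]]) <= 0) stop("degenerate width")
    list(mean = unname(co[["mu"]]), sigma = abs(unname(co[["s"]])),
         amplitude = unname(co[["A"]]), converged = TRUE)
  }, error = function(e) {
    list(mean = mean(v), sigma = max(stats::sd(v), 1), amplitude = max(counts),
         converged = FALSE)
  })
  structure(fit, class = "intensity_fit")
}

#' @export
print.intensity_fit <- function(x, ...) {
  cat(sprintf("Gaussian intensity fit: mean %.2f, sigma %.2f%s\n",
              x$mean, x$sigma,
              if (x$converged) "" else " (fallback: sample moments)"))
  invisible(x)
}

#' Intensity window from a background fit
#'
#' The adjustment window runs from `n_low` fitted SDs below the background
#' mean to `n_high` above it, clipped to the representable intensity range;
#' a degenerate window is floored so the upper bound always exceeds the
#' lower.
#'
#' @param fit an `intensity_fit`.
#' @param adjust an [adjust_params()] object.
#' @param range numeric c(lo, hi) representable intensity range.
#' @return numeric c(low_in, high_in).
#' @export
compute_bounds <- function(fit, adjust = adjust_params(),
                           range = c(0, 65535)) {
  low <- max(range[1], min(range[2], fit$mean - adjust$n_low * fit$sigma))
  high <- max(range[1], min(range[2], fit$mean + adjust$n_high * fit$sigma))
  if (high <= low) high <- min(range[2], low + max(1, fit$sigma))
  if (high <= low) low <- high - 1   # pinned at the range ceiling
  c(low_in = low, high_in = high)
}

#' Linearly rescale a frame through an intensity window
#'
#' Maps `[low_in, high_in]` onto the full output range; values outside the
#' window saturate. Pixel ordering is preserved.
#'
#' @param frame numeric matrix.
#' @param bounds numeric c(low_in, high_in) with low < high.
#' @param max_out full-scale output value (default 16-bit).
#' @return rescaled matrix of the same shape.
#' @export
rescale_frame <- function(frame, bounds, max_out = 65535) {
  if (bounds[2] <= bounds[1]) stop("bounds must satisfy low_in < high_in")
  out <- (frame - bounds[1]) / (bounds[2] - bounds[1]) * max_out
  out[out < 0] <- 0
  out[out > max_out] <- max_out
  out
}

#' Per-frame brightness/contrast normalisation of a stack
#'
#' Each frame gets its own Gaussian background fit and window, so the whole
#' movie is normalised frame by frame. The returned stack is lazy: frames
#' are adjusted on access, which keeps long movies out of memory.
#'
#' @param stack an `ngv_stack`.
#' @param adjust an [adjust_params()] object.
#' @param max_out full-scale output intensity.
#' @return a lazily adjusted `ngv_stack`.
#' @export
preprocess_stack <- function(stack, adjust = adjust_params(), max_out = 65535) {
  stack_map(stack, function(fr) {
    fit <- fit_intensity_distribution(fr)
    rescale_frame(fr, compute_bounds(fit, adjust, range = c(0, max_out)),
                  max_out = max_out)
  })
}
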