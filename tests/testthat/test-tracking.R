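det_frames <- function(xy_by_frame) {
  lapply(xy_by_frame, function(m) {
    if (is.null(m)) NULL else data.frame(x = m[, 1], y = m[, 2])
  })
}

test_that("a steadily drifting particle yields one full trajectory", {
  frames <- lapply(0:9, function(f) cbind(2 * f, 0))
  tracks <- link(det_frames(frames), link_params(max_displacement = 5))
  expect_length(tracks, 1)
  expect_equal(tracks[[1]]$frame, 0:9)
  expect_equal(tracks[[1]]$x, 2 * (0:9))
})

test_that("identity survives darkness up to the memory limit and not beyond", {
  lp <- link_params(max_displacement = 5, memory = 10)
  for (k in c(1, 5, 10, 11, 12)) {
    frames <- c(lapply(1:3, function(i) cbind(10, 10)),
                rep(list(NULL), k),
                lapply(1:3, function(i) cbind(10, 10)))
    tracks <- link(det_frames(frames), lp)
    if (k <= 10) {
      expect_length(tracks, 1)
      expect_equal(nrow(tracks[[1]]), 6)
    } else {
      expect_length(tracks, 2)
    }
  }
})

test_that("two passing particles keep their identities when separable", {
  ## particles approach to within ~6 px of each other but each continuation
  ## is far closer than max_displacement allows for a swap
  fa <- lapply(0:10, function(f) c(2 * f, 0))
  fb <- lapply(0:10, function(f) c(20 - 2 * f, 6))
  frames <- Map(function(a, b) rbind(a, b), fa, fb)
  tracks <- link(det_frames(frames), link_params(max_displacement = 3))
  expect_length(tracks, 2)
  ys <- vapply(tracks, function(tr) unique(tr$y), numeric(1))
  expect_setequal(ys, c(0, 6))
})

test_that("linking matches the exhaustive-assignment oracle on small instances", {
  set.seed(61)
  for (rep in 1:30) {
    n_particles <- sample(2:4, 1)
    n_frames <- 6
    frames <- lapply(seq_len(n_frames), function(f) {
      present <- runif(n_particles) > 0.2
      if (!any(present)) return(NULL)
      cbind(runif(sum(present), 0, 40), runif(sum(present), 0, 40))
    })
    lp <- link_params(max_displacement = 12, memory = 2)
    got <- link(det_frames(frames), lp)
    want <- bf_link(det_frames(frames), 12, 2)
    key <- function(trs) sort(vapply(trs, function(tr)
      paste(round(tr$frame, 6), round(tr$x, 6), round(tr$y, 6), collapse = "|"),
      character(1)))
    expect_equal(key(got), key(want))
  }
})

test_that("linking is invariant to detection order within a frame", {
  set.seed(62)
  frames <- lapply(1:8, function(f)
    cbind(c(5 + f, 30 - f, 60), c(10, 20, 30 + f)))
  t1 <- link(det_frames(frames), link_params(max_displacement = 5))
  shuffled <- lapply(frames, function(m) m[sample(nrow(m)), , drop = FALSE])
  t2 <- link(det_frames(shuffled), link_params(max_displacement = 5))
  key <- function(trs) sort(vapply(trs, function(tr)
    paste(tr$frame, tr$x, tr$y, collapse = "|"), character(1)))
  expect_equal(key(t1), key(t2))
})

test_that("gap filling interpolates linearly and flags filled frames", {
  traj <- data.frame(frame = c(0, 5), x = c(0, 10), y = c(0, 0),
                     detection = c(1L, 1L), interpolated = FALSE)
  filled <- fill_gaps(traj)
  expect_equal(filled$frame, 0:5)
  expect_equal(filled$x[filled$frame == 2], 4)
  expect_equal(filled$interpolated, c(FALSE, TRUE, TRUE, TRUE, TRUE, FALSE))
  ## no gaps: identity
  dense <- data.frame(frame = 0:3, x = rnorm(4), y = rnorm(4),
                      detection = 1L, interpolated = FALSE)
  expect_equal(fill_gaps(dense)$x, dense$x)
})

test_that("straight-line filling is the shortest possible in-filling", {
  set.seed(63)
  for (rep in 1:20) {
    fr <- sort(sample(0:20, 8))
    traj <- data.frame(frame = fr, x = cumsum(rnorm(8)), y = cumsum(rnorm(8)),
                       detection = 1L, interpolated = FALSE)
    filled <- fill_gaps(traj)
    plen <- function(d) sum(sqrt(diff(d$x)^2 + diff(d$y)^2))
    base <- plen(filled)
    for (alt in 1:5) {
      jitter <- filled
      gap <- which(jitter$interpolated)
      if (!length(gap)) break
      jitter$x[gap] <- jitter$x[gap] + rnorm(length(gap), 0, 0.5)
      jitter$y[gap] <- jitter$y[gap] + rnorm(length(gap), 0, 0.5)
      expect_gte(plen(jitter), base - 1e-9)
    }
  }
})

test_that("synthetic movies with blinking keep one trajectory per cell", {
  ## well-separated slow cells, dark runs well under the memory limit
  p <- simulation_params(n_cells = 12, n_frames = 60, frame_shape = c(1500, 1500),
                         blink_probability = 0.15, blink_max = 5,
                         mean_speed = 0.3, seed = 64)
  truth <- simulate_ground_truth(p)
  det <- lapply(seq_len(p$n_frames), function(f) {
    vis <- truth$nuc_visible[f, ]
    data.frame(x = truth$x[f, vis] / p$pixel_size,
               y = truth$y[f, vis] / p$pixel_size)
  })
  tracks <- link(det, link_params(max_displacement = 15, memory = 10))
  expect_equal(length(tracks), p$n_cells)
  acc <- track_link_accuracy(tracks, truth, "nuclei")
  expect_gte(acc$correct_link_fraction, 0.95)
})
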