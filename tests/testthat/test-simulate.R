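test_that("identical parameters and seed give bit-identical ground truth", {
  p <- small_movie_params(seed = 33)
  t1 <- simulate_ground_truth(p)
  t2 <- simulate_ground_truth(p)
  expect_identical(t1, t2)
  f1 <- render_frame(t1, 3, "golgi")
  f2 <- render_frame(t2, 3, "golgi")
  expect_identical(f1, f2)
})

test_that("parameter validation rejects unphysical settings", {
  expect_error(simulation_params(persistence_time = 0), "persistence_time")
  expect_error(simulation_params(labeled_fraction = 1.5), "labeled_fraction")
  expect_error(simulation_params(anisotropy = -1), "anisotropy")
})

test_that("memoryless limit decorrelates velocities within one frame", {
  p <- simulation_params(n_cells = 400, n_frames = 60,
                         frame_shape = c(8000, 8000),
                         persistence_time = 0.01, seed = 2)
  v <- vacf(as_trajectories(simulate_trajectories(p)), frame_interval = 5)
  expect_equal(v$vacf[1], 1)
  expect_lt(abs(v$vacf[2]), 0.05)
})

test_that("anisotropy scales the x step size linearly", {
  p <- simulation_params(n_cells = 300, n_frames = 100, anisotropy = 2,
                         frame_shape = c(8000, 8000), seed = 4)
  tr <- simulate_trajectories(p)
  ratio <- mean(abs(diff(tr$x))) / mean(abs(diff(tr$y)))
  expect_equal(ratio, 2, tolerance = 0.05)
})

test_that("heading persistence is recovered from the VACF semilog fit", {
  p <- open_field_params(n_cells = 1000, seed = 8)
  v <- vacf(as_trajectories(simulate_trajectories(p)), frame_interval = 5)
  tau <- fit_persistence(v)$persistence_time
  expect_equal(tau, 240, tolerance = 0.15)
})

test_that("labeling follows the configured fraction", {
  p <- simulation_params(n_cells = 100, n_frames = 2, labeled_fraction = 0.4,
                         seed = 12)
  truth <- simulate_ground_truth(p)
  expect_gt(sum(truth$labeled), 25)
  expect_lt(sum(truth$labeled), 55)
  p0 <- simulation_params(n_cells = 20, n_frames = 2, labeled_fraction = 0,
                          seed = 12)
  expect_equal(sum(simulate_ground_truth(p0)$labeled), 0)
})

test_that("Golgi placement respects offset geometry", {
  p <- simulation_params(n_cells = 40, n_frames = 5, labeled_fraction = 1,
                         ngv_offset = c(mean = 10, jitter = 0),
                         fragment_scatter = 0, seed = 6)
  paths <- simulate_trajectories(p)
  g <- place_golgi(paths, p)
  d <- sqrt((g$golgi_x - paths$x)^2 + (g$golgi_y - paths$y)^2)
  expect_equal(as.vector(d), rep(10, length(d)), tolerance = 1e-9)
  ## zero scatter: every fragment coincides with the centroid
  expect_true(all(vapply(g$fragments, function(f) all(abs(f) < 1e-9),
                         logical(1))))
  ## a tightly concentrated NGV lies along the x axis (apolar)
  p2 <- simulation_params(n_cells = 200, n_frames = 2, labeled_fraction = 1,
                          ngv_concentration = 1e6, seed = 6)
  g2 <- place_golgi(simulate_trajectories(p2), p2)
  expect_lt(truncated_sd(g2$ngv_angle)$sigma_t, 1)
})

test_that("dark runs never exceed blink_max and zero blinking means always on", {
  p <- simulation_params(n_cells = 30, n_frames = 200, blink_probability = 0.8,
                         blink_max = 3, seed = 13)
  truth <- simulate_ground_truth(p)
  worst <- max(apply(!truth$nuc_visible, 2, function(dark) {
    r <- rle(dark)
    if (any(r$values)) max(r$lengths[r$values]) else 0L
  }))
  expect_lte(worst, 3)
  p0 <- simulation_params(n_cells = 10, n_frames = 50, blink_probability = 0,
                          seed = 13)
  expect_true(all(simulate_ground_truth(p0)$nuc_visible))
})

test_that("rendering recovers ground-truth centroids", {
  p <- simulation_params(n_cells = 1, n_frames = 1, frame_shape = c(120, 120),
                         noise_sigma = 0, blink_probability = 0, labeled_fraction = 1, seed = 20)
  truth <- simulate_ground_truth(p)
  fr <- render_frame(truth, 1, "nuclei")
  det <- segment_nuclei(fr, threshold = p$background + p$nucleus_amp / 3)
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$x - truth$x[1, 1] / p$pixel_size), 1)
  expect_lt(abs(det$y - truth$y[1, 1] / p$pixel_size), 1)
})

test_that("a frame too small for its cells is reported by cell", {
  p <- simulation_params(n_cells = 2, n_frames = 1, frame_shape = c(12, 12),
                         seed = 1)
  truth <- simulate_ground_truth(p)
  expect_error(render_frame(truth, 1, "nuclei"), "frame too small for cell")
})

test_that("written movies are byte-identical across runs", {
  p <- simulation_params(n_cells = 3, n_frames = 4, frame_shape = c(120, 120),
                         labeled_fraction = 1, seed = 17)
  truth <- simulate_ground_truth(p)
  d1 <- tempfile("mov1"); d2 <- tempfile("mov2")
  render_movie(truth, d1)
  render_movie(truth, d2)
  for (f in c("nuclei.tif", "golgi.tif", "ground_truth.csv", "pairs_truth.csv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})
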