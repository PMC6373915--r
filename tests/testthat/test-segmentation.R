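test_that("a rendered ellipse is recovered with its orientation and axes", {
  p <- simulation_params(n_cells = 1, n_frames = 1, frame_shape = c(200, 200),
                         noise_sigma = 0, blink_probability = 0, nuclei_axes = c(major = 24,
                                                          minor = 12,
                                                          jitter = 0),
                         pixel_size = 0.8, seed = 51)
  truth <- simulate_ground_truth(p)
  truth$angle[1] <- 40
  truth$x[1, 1] <- 80; truth$y[1, 1] <- 80
  fr <- render_frame(truth, 1, "nuclei")
  det <- segment_nuclei(fr, threshold = p$background + p$nucleus_amp / 3)
  expect_equal(nrow(det), 1)
  expect_equal(det$orientation, 40, tolerance = 2)
  expect_equal(det$major, 24 / 0.8, tolerance = 0.1 * 24 / 0.8)
  expect_equal(det$minor, 12 / 0.8, tolerance = 0.1 * 12 / 0.8)
})

test_that("a circle is flagged degenerate and two ellipses give two detections", {
  p <- simulation_params(n_cells = 1, n_frames = 1, frame_shape = c(200, 200),
                         noise_sigma = 0, blink_probability = 0,
                         nuclei_axes = c(major = 16, minor = 16, jitter = 0),
                         seed = 52)
  truth <- simulate_ground_truth(p)
  truth$x[1, 1] <- 80; truth$y[1, 1] <- 80
  fr <- render_frame(truth, 1, "nuclei")
  det <- segment_nuclei(fr, threshold = p$background + p$nucleus_amp / 3)
  expect_equal(nrow(det), 1)
  expect_true(det$degenerate)
  expect_equal(det$major, det$minor, tolerance = 0.05 * det$major)

  p2 <- simulation_params(n_cells = 2, n_frames = 1, frame_shape = c(300, 300),
                          noise_sigma = 0, blink_probability = 0, seed = 53)
  truth2 <- simulate_ground_truth(p2)
  truth2$x[1, ] <- c(60, 180); truth2$y[1, ] <- c(60, 180)
  fr2 <- render_frame(truth2, 1, "nuclei")
  det2 <- segment_nuclei(fr2, threshold = p2$background + p2$nucleus_amp / 3)
  expect_equal(nrow(det2), 2)
})

test_that("an empty or blank frame yields no nucleus detections", {
  expect_equal(nrow(segment_nuclei(matrix(0, 50, 50))), 0)
  expect_equal(nrow(segment_nuclei(matrix(100, 50, 50), threshold = 200)), 0)
})

test_that("hard-cutoff thresholding returns exactly the bright pixels", {
  fr <- matrix(0, 40, 40)
  expect_equal(nrow(threshold_golgi(fr, max(fr) + 1)), 0)
  expect_equal(nrow(threshold_golgi(fr, -Inf)), 1600)
  fr[5:9, 11:15] <- 500          # 25 bright pixels
  co <- threshold_golgi(fr, 100)
  expect_equal(nrow(co), 25)
  expect_true(all(co[, "x"] %in% 10:14))   # 0-based columns
  expect_true(all(co[, "y"] %in% 4:8))
})

test_that("single-linkage clustering matches the transitive-closure oracle", {
  set.seed(54)
  shape <- c(100, 100)
  cutoff <- 0.08 * sqrt(sum(shape^2))
  for (rep in 1:50) {
    n <- sample(2:40, 1)
    coords <- cbind(x = sample(0:99, n, replace = TRUE),
                    y = sample(0:99, n, replace = TRUE))
    coords <- unique(coords)
    got <- cluster_golgi_pixels(coords, 0.08, shape)
    want <- split(seq_len(nrow(coords)), bf_cluster(coords, cutoff))
    want <- lapply(want, function(i) coords[i, , drop = FALSE])
    expect_equal(partition_key(got), partition_key(want))
  }
})

test_that("clustering honours trivial separations", {
  shape <- c(100, 100)
  ## two pixels farther apart than the cutoff stay separate
  co <- rbind(c(0, 0), c(90, 90))
  colnames(co) <- c("x", "y")
  expect_length(cluster_golgi_pixels(co, 0.05, shape), 2)
  ## a 1-px-spaced chain is one cluster at any sensible cutoff
  chain <- cbind(x = 0:30, y = rep(5, 31))
  expect_length(cluster_golgi_pixels(chain, 0.05, shape), 1)
  expect_length(cluster_golgi_pixels(NULL, 0.05, shape), 0)
})

test_that("the size filter drops clusters below 3 pixels", {
  clusters <- list(pixel_run(1, 0, 0), pixel_run(2, 50, 0),
                   pixel_run(3, 0, 50), pixel_run(5, 60, 60))
  det <- merge_fragments(clusters, merge_distance = 10, min_cluster_px = 3)
  expect_equal(sort(det$size), c(3, 5))
})

test_that("two nearby clusters merge into one detection", {
  a <- rbind(pixel_run(5, 0, 0), pixel_run(5, 0, 1))     # 10 px
  b <- rbind(pixel_run(5, 8, 0), pixel_run(5, 8, 1))     # 10 px, gap 4 to a
  det <- merge_fragments(list(a, b), merge_distance = 10, min_cluster_px = 3)
  expect_equal(nrow(det), 1)
  expect_equal(det$size, 20)
})

test_that("largest-first hull merging matches an independent re-implementation", {
  set.seed(55)
  for (rep in 1:40) {
    k <- sample(2:8, 1)
    clusters <- lapply(seq_len(k), function(i) {
      n <- sample(1:15, 1)
      cx <- sample(0:120, 1); cy <- sample(0:120, 1)
      unique(cbind(x = cx + sample(0:6, n, replace = TRUE),
                   y = cy + sample(0:6, n, replace = TRUE)))
    })
    md <- sample(c(5, 10, 20), 1)
    got <- merge_fragments(clusters, merge_distance = md, min_cluster_px = 3)
    want <- bf_merge(clusters, merge_distance = md, min_px = 3)
    expect_equal(partition_key(got$pixels), partition_key(want))
  }
})

test_that("merged detections partition the retained pixels", {
  set.seed(56)
  clusters <- lapply(1:6, function(i) {
    cx <- sample(0:200, 1); cy <- sample(0:200, 1)
    unique(cbind(x = cx + sample(0:5, 8, replace = TRUE),
                 y = cy + sample(0:5, 8, replace = TRUE)))
  })
  det <- merge_fragments(clusters, merge_distance = 15, min_cluster_px = 3)
  kept <- do.call(rbind, clusters[vapply(clusters, nrow, integer(1)) >= 3])
  out <- do.call(rbind, det$pixels)
  expect_equal(nrow(out), nrow(kept))
  expect_equal(sort(paste(out[, 1], out[, 2])), sort(paste(kept[, 1], kept[, 2])))
})

test_that("translation moves centroids rigidly", {
  set.seed(57)
  clusters <- lapply(1:4, function(i) {
    cx <- sample(0:80, 1); cy <- sample(0:80, 1)
    unique(cbind(x = cx + sample(0:4, 6, replace = TRUE),
                 y = cy + sample(0:4, 6, replace = TRUE)))
  })
  d0 <- merge_fragments(clusters, 12, 3)
  shifted <- lapply(clusters, function(m) m + 37)
  d1 <- merge_fragments(shifted, 12, 3)
  o0 <- order(d0$x, d0$y); o1 <- order(d1$x, d1$y)
  expect_equal(d1$x[o1], d0$x[o0] + 37)
  expect_equal(d1$y[o1], d0$y[o0] + 37)
})
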