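test_that("wrinkle-frame rotation follows the stated convention", {
  pts <- cbind(c(1, 0), c(0, 1))
  expect_equal(rotate_to_wrinkle_frame(pts, 0), cbind(x = c(1, 0), y = c(0, 1)))
  r90 <- rotate_to_wrinkle_frame(cbind(3, 4), 90)
  expect_equal(unname(r90), cbind(4, -3))
  ## rigid: pairwise distances preserved on random point sets
  set.seed(81)
  for (a in c(17, 60, 133)) {
    m <- matrix(rnorm(40), ncol = 2)
    expect_equal(as.matrix(dist(rotate_to_wrinkle_frame(m, a))),
                 as.matrix(dist(m)), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("NGV angles are apolar angles of the nucleus-to-Golgi vector", {
  n <- data.frame(frame = 0:2, x = c(0, 0, 0), y = c(0, 0, 0))
  east <- data.frame(frame = 0:2, x = c(1, -1, 1), y = c(0, 0, 1))
  a <- ngv_angle(n, east)
  expect_equal(a$angle, c(0, 0, 45))   # +x, -x (apolar), diagonal
  ## missing frames give no value
  g2 <- data.frame(frame = 5:6, x = 1, y = 0)
  expect_equal(nrow(ngv_angle(n, g2)), 0)
})

test_that("speed arithmetic and the pure-x guard are correct", {
  tr <- data.frame(frame = 0:3, x = c(0, 3, 6, 9), y = c(0, 4, 8, 12))
  s <- compute_speed(tr, pixel_size = 0.5, frame_interval = 5)
  expect_equal(s$speed, rep(0.5, 3))            # 5 px * 0.5 um / 5 min
  expect_equal(s$abs_vx, rep(0.3, 3))
  tr_x <- data.frame(frame = 0:3, x = 0:3, y = rep(1, 4))
  expect_true(is.na(attr(compute_speed(tr_x, 1, 5), "vx_vy_ratio")))
})

test_that("isotropic walks give unit velocity-component ratio", {
  p <- open_field_params(n_cells = 1000, seed = 82)
  trl <- as_trajectories(simulate_trajectories(p))
  ratios <- vapply(trl, function(tr)
    attr(compute_speed(tr, 1, 5), "vx_vy_ratio"), numeric(1))
  expect_equal(mean(ratios), 1, tolerance = 0.05)
})

test_that("MSD matches closed forms for ballistic, frozen and diffusive motion", {
  tt <- 0:50
  ball <- list(data.frame(frame = tt, x = 2 * tt, y = 0))
  m <- msd(ball, frame_interval = 1)
  expect_equal(m$msd, (2 * m$lag)^2, tolerance = 1e-9)
  frozen <- list(data.frame(frame = tt, x = rep(1, 51), y = rep(2, 51)))
  expect_true(all(msd(frozen, 1)$msd == 0))
  set.seed(83)
  walks <- lapply(1:400, function(i)
    data.frame(frame = 0:80, x = cumsum(c(0, rnorm(80, 0, 1.5))),
               y = cumsum(c(0, rnorm(80, 0, 1.5)))))
  m2 <- msd(walks, frame_interval = 1, max_lag = 20)
  expect_equal(m2$msd, 2 * 1.5^2 * m2$lag, tolerance = 0.05)
})

test_that("gyration tensor flags an all-x ensemble and matches anisotropy", {
  along_x <- list(data.frame(frame = 0:9, x = 0:9, y = rep(0, 10)))
  expect_error(gyration_ratio(along_x), "undefined")
  p <- open_field_params(n_cells = 500, seed = 84, anisotropy = 1.5)
  g <- gyration_ratio(as_trajectories(simulate_trajectories(p)))
  expect_equal(g$ratio, 1.5^2, tolerance = 0.15 * 1.5^2)
})

test_that("VACF is 1 for straight motion, ~0 for memoryless steps, bounded", {
  straight <- list(data.frame(frame = 0:30, x = 3 * (0:30), y = 2 * (0:30)))
  v <- vacf(straight, frame_interval = 1, max_lag = 10)
  expect_true(all(abs(v$vacf - 1) < 1e-9))
  set.seed(85)
  jumpy <- lapply(1:200, function(i)
    data.frame(frame = 0:60, x = cumsum(c(0, rnorm(60))),
               y = cumsum(c(0, rnorm(60)))))
  v2 <- vacf(jumpy, frame_interval = 1, max_lag = 20)
  expect_equal(v2$vacf[1], 1)
  expect_true(all(abs(v2$vacf[-1]) < 0.05))
  expect_true(all(v2$vacf >= -1 & v2$vacf <= 1))
})

test_that("persistence fitting inverts an exact exponential and flags flat curves", {
  lags <- seq(0, 300, by = 5)
  curve <- data.frame(lag = lags, vacf = exp(-lags / 120))
  expect_equal(fit_persistence(curve)$persistence_time, 120, tolerance = 1e-6)
  flat <- data.frame(lag = lags, vacf = rep(1, length(lags)))
  expect_true(is.na(fit_persistence(flat)$persistence_time))
  expect_error(fit_persistence(data.frame(lag = 0:1, vacf = c(1, 0.5))),
               "at least 3")
})

test_that("group comparison applies the Bonferroni factor and caps at 1", {
  same <- list(a = c(1, 2, 3, 4, 5), b = c(1, 2, 3, 4, 5))
  res <- compare_groups(same)
  expect_equal(res$pairwise$p_adjusted, 1)
  sep <- list(lo = 1:10, hi = 101:110)
  expect_lt(compare_groups(sep)$kruskal$p.value, 0.01)
  three <- list(a = rnorm(10), b = rnorm(10), c = rnorm(10))
  expect_equal(compare_groups(three)$n_comparisons, 3)
  expect_error(compare_groups(list(a = 1:5)), "at least 2 groups")
  expect_error(compare_groups(list(a = 1:5, b = numeric(0))), "at least 2 values")
})
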