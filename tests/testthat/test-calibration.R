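test_that("sphere center is recovered exactly from noiseless surface points", {
  set.seed(21)
  center <- c(100, -50, 2000)
  pts <- sweep(240 * r_unit_sphere(200), 2, center, "+")
  fit <- ransac_sphere_center(pts, radius = 240, seed = 7)
  expect_equal(fit$center, center, tolerance = 1e-6)
  expect_length(fit$inlier_indices, 200)
})

test_that("RANSAC excludes box outliers and matches the clean-subset oracle", {
  set.seed(22)
  center <- c(100, -50, 2000)
  clean <- sweep(240 * r_unit_sphere(200), 2, center, "+")
  outliers <- cbind(stats::runif(20, -500, 500), stats::runif(20, -500, 500),
                    stats::runif(20, 1500, 2500))
  pts <- rbind(clean, outliers)
  fit <- ransac_sphere_center(pts, radius = 240, seed = 3)
  oracle <- lsq_sphere_center(clean)
  # a box outlier may land on the sphere surface by chance; the center must
  # still agree with the clean-subset oracle to well below the inlier
  # tolerance and every clean point must be retained
  expect_equal(fit$center, oracle, tolerance = 1e-3)
  expect_lt(sqrt(sum((fit$center - center)^2)), 1)
  expect_true(all(seq_len(200) %in% fit$inlier_indices))
  # reproducible given the seed
  fit2 <- ransac_sphere_center(pts, radius = 240, seed = 3)
  expect_identical(fit$center, fit2$center)
  expect_identical(fit$inlier_indices, fit2$inlier_indices)
})

test_that("sphere fitting needs at least 4 points", {
  expect_error(ransac_sphere_center(diag(3), radius = 240),
               "insufficient data")
})

test_that("trajectory construction keeps only frames seen by every sensor", {
  set.seed(23)
  path <- cbind(seq(0, 900, length.out = 10), 100, 2000)
  mk <- function(sid, frames) tibble::tibble(
    frame_index = frames, sensor_id = sid,
    x_mm = path[frames + 1, 1], y_mm = path[frames + 1, 2],
    z_mm = path[frames + 1, 3])
  centroids <- dplyr::bind_rows(
    mk("A", 0:9), mk("B", setdiff(0:9, 3)), mk("C", 0:9))
  trajs <- build_trajectories(centroids, master_id = "A")
  expect_named(trajs, c("B", "C"))
  expect_equal(trajs$B$n, 9)
  expect_equal(nrow(trajs$B$points_master), 9)
  # aligned index-by-index against the master
  expect_equal(trajs$C$points_master, trajs$C$points_target)
  # no common frames
  bad <- dplyr::bind_rows(mk("A", 0:4), mk("B", 5:9))
  expect_error(build_trajectories(bad, "A"), "insufficient correspondences")
})

test_that("rigid registration recovers constructed transforms exactly", {
  master <- rbind(c(0, 0, 0), c(1000, 0, 0), c(0, 1000, 0), c(0, 0, 1000))
  # identity case
  fit0 <- estimate_rigid_transform(master, master)
  expect_lt(max(abs(fit0$transform$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(fit0$transform$translation)), 1e-9)
  # target = master rotated -90 deg about z then shifted
  Rz <- rotation_z(-pi / 2)
  target <- sweep(master %*% t(Rz), 2, c(-1000, -2000, -3000), "+")
  fit <- estimate_rigid_transform(target, master)
  expect_lt(fit$rms_residual_mm, 1e-6)
  expect_equal(rt_apply(fit$transform, target), master, tolerance = 1e-6)
  expect_false(fit$reflection_corrected)
})

test_that("registration rejects degenerate or mismatched input", {
  line <- cbind(0:9 * 100, 0, 0)
  expect_error(estimate_rigid_transform(line, line), "degenerate")
  expect_error(estimate_rigid_transform(matrix(0, 4, 3), matrix(0, 5, 3)),
               "differ in length")
  expect_error(estimate_rigid_transform(matrix(0, 2, 3), matrix(0, 2, 3)),
               "at least 3")
})

test_that("noisy fits always return a proper rotation", {
  set.seed(24)
  for (i in 1:50) {
    R <- random_rotation()
    master <- matrix(stats::rnorm(30, sd = 300), 10, 3)
    # near-planar geometry plus noise stresses the reflection guard
    master[, 3] <- master[, 3] * 0.01
    target <- sweep((master + matrix(stats::rnorm(30, sd = 20), 10, 3)) %*% R,
                    2, stats::rnorm(3, sd = 100), "+")
    fit <- estimate_rigid_transform(target, master)
    Rhat <- fit$transform$rotation
    expect_lt(max(abs(crossprod(Rhat) - diag(3))), 1e-9)
    expect_equal(det(Rhat), 1, tolerance = 1e-9)
    expect_equal(sort(fit$singular_values, decreasing = TRUE),
                 fit$singular_values)
  }
})

test_that("calibrate_sensors recovers a multi-sensor rig end-to-end", {
  set.seed(25)
  n <- 1000
  path <- cbind(stats::rnorm(n, 0, 400), stats::rnorm(n, 0, 400),
                stats::rnorm(n, 2000, 300))
  transforms <- list(
    A = rt_identity(),
    B = rigid_transform(random_rotation(), c(500, -300, 100)),
    C = rigid_transform(random_rotation(), c(-800, 200, -50)))
  centroids <- dplyr::bind_rows(lapply(names(transforms), function(sid) {
    # each sensor sees the path in its own coordinates
    local <- rt_apply(rt_inverse(transforms[[sid]]), path)
    tibble::tibble(frame_index = seq_len(n) - 1L, sensor_id = sid,
                   x_mm = local[, 1], y_mm = local[, 2], z_mm = local[, 3])
  }))
  cal <- calibrate_sensors(centroids, master_id = "A")
  expect_equal(nrow(cal), 3)
  expect_equal(cal$n[cal$sensor_id == "B"], 1000)
  for (sid in c("B", "C")) {
    tr <- cal$transform[[which(cal$sensor_id == sid)]]
    expect_lt(max(abs(tr$rotation - transforms[[sid]]$rotation)), 1e-9)
    expect_lt(max(abs(tr$translation - transforms[[sid]]$translation)), 1e-6)
  }
})

test_that("tidy and glance summarize a rigid fit", {
  set.seed(26)
  master <- matrix(stats::rnorm(30, sd = 500), 10, 3)
  fit <- estimate_rigid_transform(master, master)
  td <- generics::tidy(fit)
  expect_equal(td$term, c("theta_x_rad", "theta_y_rad", "theta_z_rad",
                          "t_x_mm", "t_y_mm", "t_z_mm"))
  expect_equal(td$estimate, rep(0, 6), tolerance = 1e-9)
  gl <- generics::glance(fit)
  expect_equal(gl$n, 10)
  expect_equal(gl$rms_residual_mm, 0, tolerance = 1e-9)
})

test_that("the marker plate defines the global frame", {
  plate <- rbind(c(0, 100, 0), c(0, 0, 0), c(100, 0, 0), c(100, 100, 0))
  tr <- marker_frame(plate, up_hint = c(0, 0, 1))
  expect_lt(max(abs(tr$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(tr$translation)), 1e-9)
  # translated plate: rotation unchanged, marker 1 maps to the origin
  tr2 <- marker_frame(sweep(plate, 2, c(5, 5, 5), "+"), up_hint = c(0, 0, 1))
  expect_lt(max(abs(tr2$rotation - diag(3))), 1e-9)
  expect_equal(rt_apply(tr2, c(5, 5, 5)), c(0, 0, 0), tolerance = 1e-9)
  # arbitrarily rotated plate maps back to the axis-aligned configuration
  set.seed(27)
  R <- random_rotation()
  shift <- c(40, -70, 25)
  moved <- sweep(plate %*% t(R), 2, shift, "+")
  tr3 <- marker_frame(moved, up_hint = as.numeric(R %*% c(0, 0, 1)))
  expect_equal(rt_apply(tr3, moved), plate, tolerance = 1e-9,
               ignore_attr = TRUE)
  # collinear markers are degenerate
  bad <- rbind(c(2, 0, 0), c(0, 0, 0), c(1, 0, 0), c(3, 0, 0))
  expect_error(marker_frame(bad), "collinear")
})
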