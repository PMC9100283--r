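test_that("the squat drops the pelvis sinusoidally with fixed ankles", {
  spec <- gesture_spec("squat", n_frames = 300, amplitude = 300,
                       period_s = 10)
  truth <- generate_gesture(spec)
  pelvis_z <- truth$z_mm[truth$joint == "pelvis"]
  expect_equal(max(pelvis_z) - min(pelvis_z), 300, tolerance = 1e-6)
  t <- truth$timestamp_s[truth$joint == "pelvis"]
  expect_equal(pelvis_z, max(pelvis_z) - 150 * (1 - cos(2 * pi * t / 10)),
               tolerance = 1e-9)
  for (j in c("ankle_L", "ankle_R")) {
    for (col in c("x_mm", "y_mm", "z_mm")) {
      expect_equal(diff(range(truth[[col]][truth$joint == j])), 0)
    }
  }
})

test_that("bone lengths are constant across frames for every gesture", {
  bones <- bone_table()
  for (g in benchmark_gestures) {
    truth <- generate_gesture(gesture_spec(g, n_frames = 120, seed = 7))
    wide <- tidyr::pivot_wider(truth, id_cols = "frame_index",
                               names_from = "joint",
                               values_from = c("x_mm", "y_mm", "z_mm"))
    for (b in seq_len(nrow(bones))) {
      len <- sqrt(
        (wide[[paste0("x_mm_", bones$from[b])]] -
           wide[[paste0("x_mm_", bones$to[b])]])^2 +
        (wide[[paste0("y_mm_", bones$from[b])]] -
           wide[[paste0("y_mm_", bones$to[b])]])^2 +
        (wide[[paste0("z_mm_", bones$from[b])]] -
           wide[[paste0("z_mm_", bones$to[b])]])^2)
      expect_lt(max(abs(len - len[1])), 1e-6)
    }
  }
})

test_that("constant-speed walking covers speed times duration", {
  spec <- gesture_spec("walking", n_frames = 1000, frame_rate_hz = 30,
                       speed_mm_s = 1200)
  truth <- generate_gesture(spec)
  px <- truth$x_mm[truth$joint == "pelvis"]
  expect_equal(px[1000] - px[1], 1200 * 999 / 30, tolerance = 1e-9)
  # within 1% of speed x nominal duration
  expect_equal(px[1000] - px[1], 1200 * 1000 / 30, tolerance = 0.01)
})

test_that("all sixteen joints are present in every frame", {
  truth <- generate_gesture(gesture_spec("lunge", n_frames = 50))
  counts <- table(truth$frame_index)
  expect_true(all(counts == 16))
  expect_setequal(unique(truth$joint), joint_names())
})

test_that("a noiseless single sensor reproduces the ground truth", {
  truth <- generate_gesture(gesture_spec("jump", n_frames = 20))
  quiet <- noise_model(jitter_sigma_mm = 0, occluded_jitter_sigma_mm = 0,
                       outlier_prob = 0, swap_prob = 0, dropout_prob = 0,
                       occlusion_angle_deg = 180, seed = 1)
  stream <- observe(truth, sensor_rig(1), quiet)
  expect_equal(stream$x_mm, truth$x_mm)
  expect_equal(stream$y_mm, truth$y_mm)
  expect_equal(stream$z_mm, truth$z_mm)
  expect_true(all(stream$confidence == "medium"))
})

test_that("jitter matches the isotropic 3D Gaussian RMS", {
  truth <- generate_gesture(gesture_spec("squat", n_frames = 500))
  noisy <- noise_model(jitter_sigma_mm = 5, occluded_jitter_sigma_mm = 5,
                       outlier_prob = 0, swap_prob = 0, dropout_prob = 0,
                       occlusion_angle_deg = 180, seed = 13)
  stream <- observe(truth, sensor_rig(4), noisy)
  err <- sqrt((stream$x_mm - rep(truth$x_mm, 4))^2 +
                (stream$y_mm - rep(truth$y_mm, 4))^2 +
                (stream$z_mm - rep(truth$z_mm, 4))^2)
  expect_equal(sqrt(mean(err^2)), 5 * sqrt(3), tolerance = 0.05)
})

test_that("planted permanent swaps are detected and corrected", {
  truth <- generate_gesture(gesture_spec("squat", n_frames = 30))
  swapper <- noise_model(jitter_sigma_mm = 0, occluded_jitter_sigma_mm = 0,
                         outlier_prob = 0, swap_prob = 1, dropout_prob = 0,
                         occlusion_angle_deg = 180, seed = 2)
  clean <- noise_model(jitter_sigma_mm = 0, occluded_jitter_sigma_mm = 0,
                       outlier_prob = 0, swap_prob = 0, dropout_prob = 0,
                       occlusion_angle_deg = 180, seed = 3)
  rig <- sensor_rig(4)
  s2 <- observe(truth, rig[2, ], swapper)
  others <- observe(truth, rig[-2, ], clean)
  # sensor 2's elbow labels are exchanged on every frame
  tr_r <- truth[truth$joint == "elbow_R", ]
  expect_equal(s2$x_mm[s2$joint == "elbow_L"], tr_r$x_mm)
  expect_true(all(s2$confidence[s2$joint == "elbow_L"] == "low"))
  # arrangement restores them using the three clean sensors
  fixed <- arrange_frame(dplyr::bind_rows(others, s2))
  fx <- fixed[fixed$sensor_id == "s2" & fixed$joint == "elbow_R", ]
  expect_equal(fx$x_mm, tr_r$x_mm)
  expect_equal(fx$y_mm, tr_r$y_mm)
})

test_that("observation is deterministic in the seed", {
  truth <- generate_gesture(gesture_spec("walking", n_frames = 40))
  rig <- sensor_rig(3)
  a <- observe(truth, rig, noise_model(seed = 5))
  b <- observe(truth, rig, noise_model(seed = 5))
  c <- observe(truth, rig, noise_model(seed = 6))
  expect_identical(a, b)
  expect_false(identical(a$x_mm, c$x_mm))
})

test_that("empirical outlier rates converge to the configured probability", {
  truth <- generate_gesture(gesture_spec("squat", n_frames = 1000))
  noisy <- noise_model(jitter_sigma_mm = 0, occluded_jitter_sigma_mm = 0,
                       outlier_prob = 0.15, swap_prob = 0, dropout_prob = 0,
                       occlusion_angle_deg = 0, seed = 17)
  stream <- observe(truth, sensor_rig(4), noisy)
  displaced <- abs(stream$x_mm - rep(truth$x_mm, 4)) +
    abs(stream$y_mm - rep(truth$y_mm, 4)) +
    abs(stream$z_mm - rep(truth$z_mm, 4)) > 0
  # 64,000 joint-frames; binomial tolerance
  expect_equal(mean(displaced), 0.15, tolerance = 0.02)
})

test_that("occlusion degrades back-facing sensors only", {
  truth <- generate_gesture(gesture_spec("squat", n_frames = 10))
  noisy <- noise_model(jitter_sigma_mm = 0, occluded_jitter_sigma_mm = 0,
                       outlier_prob = 0, swap_prob = 0, dropout_prob = 0,
                       occlusion_angle_deg = 90, seed = 4)
  rig <- sensor_rig(4) # azimuths 45, 135, 225, 315; subject faces +x
  stream <- observe(truth, rig, noisy)
  conf <- tapply(stream$confidence, stream$sensor_id,
                 function(x) mean(x == "medium"))
  expect_equal(as.vector(conf[c("s1", "s4")]), c(1, 1)) # frontal sensors
  expect_equal(as.vector(conf[c("s2", "s3")]), c(0, 0)) # behind the subject
})

test_that("a benchmark round-trips through its files deterministically", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  spec <- gesture_spec("squat", n_frames = 25)
  rig <- sensor_rig(4)
  noise <- noise_model(seed = 8)
  out1 <- make_benchmark(spec, rig, noise, dir1)
  out2 <- make_benchmark(spec, rig, noise, dir2)
  expect_length(out1$streams, 4)
  for (i in seq_along(out1$streams)) {
    expect_identical(readLines(out1$streams[i]), readLines(out2$streams[i]))
  }
  manifest <- jsonlite::read_json(out1$manifest)
  expect_equal(manifest$noise$seed, 8)
  # read back equals the in-memory stream
  stream <- observe(generate_gesture(spec), rig, noise)
  got <- dplyr::bind_rows(lapply(out1$streams, read_skeleton_stream))
  expect_equal(got$x_mm, stream$x_mm, tolerance = 1e-9)
  expect_equal(got$confidence, stream$confidence)
})
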