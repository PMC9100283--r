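test_that("reference position follows the confidence fallback rule", {
  pos <- rbind(c(0, 0, 0), c(10, 0, 0), c(1000, 0, 0))
  expect_equal(reference_position(pos, c("medium", "medium", "low")),
               c(5, 0, 0))
  pos2 <- rbind(c(0, 0, 0), c(20, 0, 0))
  expect_equal(reference_position(pos2, c("low", "low")), c(10, 0, 0))
  expect_null(reference_position(pos2, c("none", "none")))
  expect_null(reference_position(matrix(0, 0, 3), character(0)))
})

test_that("the pair check flags swapped labels and keeps ties", {
  r1 <- check_pair(c(100, 0, 0), c(101, 0, 0), c(-99, 0, 0))
  expect_equal(r1$d_correct, 1)
  expect_equal(r1$d_wrong, 199)
  expect_false(r1$swapped)
  r2 <- check_pair(c(100, 0, 0), c(-98, 1, 0), c(99, -2, 0))
  expect_equal(r2$d_correct, sqrt(198^2 + 1), tolerance = 1e-12)
  expect_equal(r2$d_wrong, sqrt(1 + 4), tolerance = 1e-12)
  expect_true(r2$swapped)
  # identical targets tie and are conservatively left alone
  r3 <- check_pair(c(100, 0, 0), c(50, 0, 0), c(50, 0, 0))
  expect_equal(r3$d_correct, r3$d_wrong)
  expect_false(r3$swapped)
})

test_that("arrangement leaves consistent frames untouched", {
  set.seed(41)
  frame <- plant_swap_frame(0L, c(150, 0, 1000), c(-150, 0, 1000),
                            swapped_sensors = integer(0))
  out <- arrange_frame(frame)
  expect_equal(out$x_mm, frame$x_mm)
  expect_false(any(out$swapped))
})

test_that("planted per-sensor swaps are corrected against the reference", {
  set.seed(42)
  hits <- 0L
  for (i in 1:100) {
    frame <- plant_swap_frame(0L, c(150, 0, 1000), c(-150, 0, 1000),
                              swapped_sensors = sample(4, 1))
    out <- arrange_frame(frame)
    swapped_rows <- which(out$swapped)
    # the corrected stream must agree with anatomical truth: right joints
    # near +x, left joints near -x
    ok <- all(sign(out$x_mm[out$joint == "wrist_R"]) == 1) &&
      all(sign(out$x_mm[out$joint == "wrist_L"]) == -1)
    hits <- hits + ok
    expect_true(length(swapped_rows) %% 2 == 0)
  }
  expect_equal(hits, 100L)
})

test_that("two swapped sensors are corrected when mediums set the reference", {
  set.seed(43)
  for (i in 1:20) {
    frame <- plant_swap_frame(0L, c(150, 0, 1000), c(-150, 0, 1000),
                              swapped_sensors = sample(4, 2))
    out <- arrange_frame(frame)
    expect_true(all(out$x_mm[out$joint == "wrist_R"] > 0))
    expect_true(all(out$x_mm[out$joint == "wrist_L"] < 0))
  }
})

test_that("arrangement is idempotent", {
  set.seed(44)
  for (i in 1:20) {
    frame <- plant_swap_frame(i, c(150, 0, 1000), c(-150, 0, 1000),
                              swapped_sensors = sample(4, sample(0:2, 1)))
    once <- arrange_frame(frame)
    twice <- arrange_frame(once[, names(frame)])
    expect_equal(twice$x_mm, once$x_mm)
    expect_equal(twice$confidence, once$confidence)
    expect_false(any(twice$swapped))
  }
})

test_that("merging returns the winning-cluster sensor centroid", {
  # consensus
  res <- merge_joint(matrix(0, 4, 3), eps_mm = 100)
  expect_equal(res$position, c(0, 0, 0))
  expect_equal(res$n_contributing, 4)
  expect_equal(res$status, "merged")
  # outlier excluded; auxiliary candidates anchor but don't shift the centroid
  cands <- rbind(c(0, 0, 0), c(20, 0, 0), c(40, 0, 0), c(500, 500, 500))
  res2 <- merge_joint(cands, reference = c(20, 0, 0), previous = c(20, 0, 0),
                      eps_mm = 100)
  expect_equal(res2$position, c(20, 0, 0))
  expect_equal(res2$n_contributing, 3)
  # previous-position smoothing candidate breaks the 1-vs-1 tie
  res3 <- merge_joint(rbind(c(0, 0, 0), c(500, 0, 0)),
                      previous = c(10, 0, 0), eps_mm = 100)
  expect_equal(res3$position, c(0, 0, 0))
  expect_equal(res3$n_contributing, 1)
  # nothing at all
  res4 <- merge_joint(matrix(0, 0, 3), eps_mm = 100)
  expect_equal(res4$status, "missing")
  res5 <- merge_joint(matrix(0, 0, 3), previous = c(1, 2, 3), eps_mm = 100)
  expect_equal(res5$status, "predicted_only")
  expect_equal(res5$position, c(1, 2, 3))
})

test_that("merged positions lie inside the candidate convex hull", {
  set.seed(45)
  for (i in 1:200) {
    n <- sample(1:6, 1)
    cands <- matrix(stats::rnorm(3 * n, sd = 200), n, 3)
    prev <- if (stats::runif(1) < 0.5) stats::rnorm(3, sd = 200) else NULL
    ref <- if (stats::runif(1) < 0.5) stats::rnorm(3, sd = 200) else NULL
    res <- merge_joint(cands, reference = ref, previous = prev,
                       eps_mm = stats::runif(1, 20, 400))
    if (res$status == "merged") {
      # a centroid of a subset of candidates stays in their bounding box
      expect_true(all(res$position >= apply(cands, 2, min) - 1e-9))
      expect_true(all(res$position <= apply(cands, 2, max) + 1e-9))
    }
  }
})

test_that("variants disagree exactly as designed on a planted outlier", {
  pose <- generate_gesture(gesture_spec("squat", n_frames = 1))
  frame <- consensus_frame(pose, n_sensors = 4)
  idx <- which(frame$sensor_id == "s4" & frame$joint == "wrist_R")
  frame$x_mm[idx] <- frame$x_mm[idx] + 500
  truth_w <- pose[pose$joint == "wrist_R", ]
  for (v in c("A1", "A3", "A4", "A5")) {
    merged <- fuse_frame(frame, fusion_config(v))$merged
    got <- merged[merged$joint == "wrist_R", ]
    shift <- got$x_mm - truth_w$x_mm
    if (v == "A1") {
      expect_equal(shift, 125) # mean over 3 good + 1 displaced sensor
    } else {
      expect_equal(shift, 0, tolerance = 1e-9)
      expect_equal(got$n_contributing, 3)
    }
    # all other joints are consensus for every variant
    others <- merged[merged$joint != "wrist_R", ]
    expect_equal(others$x_mm,
                 pose$x_mm[match(others$joint, pose$joint)],
                 tolerance = 1e-9)
  }
})

test_that("all-sensor dropout of a joint yields predicted_only", {
  frame0 <- consensus_frame(n_sensors = 3, frame_index = 0L)
  frame1 <- consensus_frame(n_sensors = 3, frame_index = 1L)
  frame1$confidence[frame1$joint == "ankle_L"] <- "none"
  for (v in c("A4", "A5")) {
    cfg <- fusion_config(v)
    st <- fuse_frame(frame0, cfg)
    out <- fuse_frame(frame1, cfg, state = st$state)$merged
    row <- out[out$joint == "ankle_L", ]
    expect_equal(row$status, "predicted_only")
    expect_true(is.finite(row$x_mm))
  }
})

test_that("a one-frame sequence equals a single fuse_frame call", {
  frame <- consensus_frame(n_sensors = 4)
  cfg <- fusion_config("A5")
  expect_equal(fuse_sequence(frame, cfg), fuse_frame(frame, cfg)$merged)
})

test_that("frames missing from every sensor are emitted as predictions", {
  frames <- dplyr::bind_rows(
    consensus_frame(frame_index = 5L),
    consensus_frame(frame_index = 6L),
    consensus_frame(frame_index = 8L))
  out <- fuse_sequence(frames, fusion_config("A4"))
  gap <- out[out$frame_index == 7, ]
  expect_equal(nrow(gap), 16)
  expect_true(all(gap$status == "predicted_only"))
  expect_true(all(is.finite(gap$x_mm)))
})

test_that("sustained dropout flags the joint missing after the cutoff", {
  frames <- dplyr::bind_rows(lapply(0:6, function(f) {
    fr <- consensus_frame(frame_index = f)
    if (f > 0) fr$confidence[fr$joint == "head"] <- "none"
    fr
  }))
  out <- fuse_sequence(frames, fusion_config("A4", max_predict_frames = 3))
  head_track <- out[out$joint == "head", ]
  expect_equal(head_track$status,
               c("merged", rep("predicted_only", 3), rep("missing", 3)))
  expect_true(all(is.na(head_track$x_mm[head_track$status == "missing"])))
})

test_that("shuffled frame order raises a stream-order error", {
  frames <- dplyr::bind_rows(consensus_frame(frame_index = 1L),
                             consensus_frame(frame_index = 0L))
  expect_error(fuse_sequence(frames, fusion_config("A1")), "stream-order")
})

test_that("the A5 engine matches an R-level Kalman pass over A4 output", {
  set.seed(46)
  truth <- generate_gesture(gesture_spec("random_movement", n_frames = 50))
  stream <- observe(truth, sensor_rig(3), noise_model(seed = 9))
  a4 <- fuse_sequence(stream, fusion_config("A4"))
  a5 <- fuse_sequence(stream, fusion_config("A5"))
  cfg <- kalman_config()
  for (j in c("pelvis", "wrist_L", "ankle_R")) {
    meas <- a4[a4$joint == j, ]
    got <- a5[a5$joint == j, ]
    state <- NULL
    for (i in seq_len(nrow(meas))) {
      z <- if (meas$status[i] == "merged")
        c(meas$x_mm[i], meas$y_mm[i], meas$z_mm[i]) else NULL
      step <- kalman_step(state, z, cfg)
      state <- step$state
      expect_equal(c(got$x_mm[i], got$y_mm[i], got$z_mm[i]), step$tracked,
                   tolerance = 1e-9)
    }
  }
})
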