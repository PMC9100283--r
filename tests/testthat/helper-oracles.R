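# Independent oracles and fixture builders used across the suite.

# Brute-force DBSCAN oracle for min_neighbors = 1: connected components of
# the closed eps-neighborhood graph, found by breadth-first search on the
# full distance matrix.
brute_components <- function(points, eps) {
  n <- nrow(points)
  if (n == 0) return(integer(0))
  adj <- as.matrix(stats::dist(points)) <= eps
  labels <- rep(0L, n)
  k <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L) next
    k <- k + 1L
    queue <- i
    labels[i] <- k
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(adj[v, ] & labels == 0L)
      labels[nb] <- k
      queue <- c(queue, nb)
    }
  }
  labels
}

# TRUE when two labelings define the same partition (up to label names)
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(tapply(b, a, function(x) length(unique(x))) == 1) &&
    all(tapply(a, b, function(x) length(unique(x))) == 1)
}

# independent algebraic sphere fit (unknown radius) by linear least squares:
# x^2+y^2+z^2 = 2 c.p + (r^2 - |c|^2)
lsq_sphere_center <- function(points) {
  A <- cbind(2 * points, 1)
  b <- rowSums(points^2)
  as.numeric(solve(crossprod(A), crossprod(A, b)))[1:3]
}

# uniform random rotation (axis-angle with random axis/angle)
random_rotation <- function() {
  axis <- stats::rnorm(3)
  axis <- axis / sqrt(sum(axis^2))
  rotation_about_test(axis, stats::runif(1, 0, 2 * pi))
}

rotation_about_test <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# one-frame stream with a planted left/right misorientation on a single
# mirrored pair: `n_sensors` sensors observe a right joint at `right_pos`
# and a left joint at `left_pos` (separation set by the caller) with
# Gaussian jitter; the sensors in `swapped_sensors` report the pair with
# exchanged labels and low confidence (occlusion-time estimates)
plant_swap_frame <- function(frame_index, right_pos, left_pos,
                             swapped_sensors, n_sensors = 4,
                             jitter_sd = 5, pair = c("wrist_R", "wrist_L")) {
  rows <- lapply(seq_len(n_sensors), function(s) {
    r_obs <- right_pos + stats::rnorm(3, 0, jitter_sd)
    l_obs <- left_pos + stats::rnorm(3, 0, jitter_sd)
    swapped <- s %in% swapped_sensors
    tibble::tibble(
      frame_index = frame_index,
      sensor_id = sprintf("s%d", s),
      joint = pair,
      x_mm = if (swapped) c(l_obs[1], r_obs[1]) else c(r_obs[1], l_obs[1]),
      y_mm = if (swapped) c(l_obs[2], r_obs[2]) else c(r_obs[2], l_obs[2]),
      z_mm = if (swapped) c(l_obs[3], r_obs[3]) else c(r_obs[3], l_obs[3]),
      confidence = if (swapped) "low" else "medium"
    )
  })
  dplyr::bind_rows(rows)
}

# full-skeleton one-frame stream where every sensor reports the same pose
consensus_frame <- function(pose = NULL, n_sensors = 4, frame_index = 0L) {
  if (is.null(pose)) {
    pose <- generate_gesture(gesture_spec("squat", n_frames = 1))
  }
  fi <- as.integer(frame_index)
  dplyr::bind_rows(lapply(seq_len(n_sensors), function(s) {
    dplyr::mutate(pose[, c("frame_index", "joint", "x_mm", "y_mm", "z_mm")],
                  frame_index = fi,
                  sensor_id = sprintf("s%d", s), confidence = "medium")
  }))
}

# default benchmark conditions shared by the structural-reproduction tests
benchmark_noise <- function(seed) noise_model(seed = seed)
benchmark_gestures <- c("hands_up_down", "jump", "squat", "lunge",
                        "walking", "random_movement")
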