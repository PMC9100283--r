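#' Gesture specification for the synthetic motion generator
#'
#' Defines one of six kinematic gesture templates: both hands up and down,
#' jump, squat, lunge, walking, and random movement (gentle swaying in a
#' standing pose). Templates are analytic toys, not biomechanical models:
#' their job is to exercise the fusion pipeline under motion while keeping
#' every bone length exactly constant. The default amplitudes and periods
#' are deliberately gentle (peak joint speeds on the order of 50-100 mm/s)
#' so the constant-position Kalman tracker operates in its assumed
#' near-stationary regime; see the methods vignette.
#'
#' @param gesture One of `"hands_up_down"`, `"jump"`, `"squat"`, `"lunge"`,
#'   `"walking"`, `"random_movement"`.
#' @param n_frames Number of frames (default 1000).
#' @param frame_rate_hz Capture rate (default 30).
#' @param amplitude Gesture amplitude: radians of arm elevation for
#'   `hands_up_down`; millimeters otherwise (peak-to-peak pelvis excursion
#'   for `squat`/`jump`, forward shift for `lunge`, sway half-range for
#'   `walking`, perturbation scale for `random_movement`). `NULL` uses the
#'   per-gesture default.
#' @param period_s Gesture period, seconds (`NULL` = per-gesture default).
#' @param speed_mm_s For `walking` only: when set, the pelvis translates at
#'   this constant speed along x instead of oscillating in place.
#' @param seed Seed for the smooth random perturbations of
#'   `random_movement` (ignored by other gestures).
#' @param subject Named list of segment lengths (mm); see defaults in the
#'   source. All lengths must be positive.
#' @return A `gesture_spec` object.
#' @export
gesture_spec <- function(gesture = c("hands_up_down", "jump", "squat",
                                     "lunge", "walking", "random_movement"),
                         n_frames = 1000L, frame_rate_hz = 30,
                         amplitude = NULL, period_s = NULL,
                         speed_mm_s = NULL, seed = 0L,
                         subject = subject_dims()) {
  gesture <- match.arg(gesture)
  stopifnot(n_frames >= 1, frame_rate_hz > 0,
            all(unlist(subject) > 0))
  defaults <- list(
    hands_up_down   = list(amplitude = 0.7, period_s = 14),
    jump            = list(amplitude = 80,  period_s = 5),
    squat           = list(amplitude = 200, period_s = 10),
    lunge           = list(amplitude = 150, period_s = 10),
    walking         = list(amplitude = 200, period_s = 16),
    random_movement = list(amplitude = 10,  period_s = 8)
  )[[gesture]]
  structure(list(
    gesture = gesture,
    n_frames = as.integer(n_frames),
    frame_rate_hz = frame_rate_hz,
    amplitude = if (is.null(amplitude)) defaults$amplitude else amplitude,
    period_s = if (is.null(period_s)) defaults$period_s else period_s,
    speed_mm_s = speed_mm_s,
    seed = as.integer(seed),
    subject = subject
  ), class = "gesture_spec")
}

#' @rdname gesture_spec
#' @export
subject_dims <- function() {
  list(
    pelvis_z = 1000, hip_z = 950, hip_halfwidth = 100,
    thigh = 430, shank = 430, ankle_z = 90,
    spine_z = 1150, neck_z = 1450, head_z = 1600,
    shoulder_z = 1400, shoulder_halfwidth = 180,
    upper_arm = 280, forearm = 250, arm_rest_rad = 0.1
  )
}

# standing reference pose: one row per joint, z up, x forward, y left
base_pose <- function(subject = subject_dims()) {
  s <- subject
  arm_dir <- c(0, sin(s$arm_rest_rad), -cos(s$arm_rest_rad))
  pose <- rbind(
    pelvis = c(0, 0, s$pelvis_z),
    spine_naval = c(0, 0, s$spine_z),
    neck = c(0, 0, s$neck_z),
    head = c(0, 0, s$head_z),
    shoulder_L = c(0, s$shoulder_halfwidth, s$shoulder_z),
    shoulder_R = c(0, -s$shoulder_halfwidth, s$shoulder_z),
    hip_L = c(0, s$hip_halfwidth, s$hip_z),
    hip_R = c(0, -s$hip_halfwidth, s$hip_z),
    elbow_L = c(0, s$shoulder_halfwidth, s$shoulder_z) +
      s$upper_arm * (arm_dir * c(1, 1, 1)),
    elbow_R = c(0, -s$shoulder_halfwidth, s$shoulder_z) +
      s$upper_arm * (arm_dir * c(1, -1, 1)),
    wrist_L = c(0, s$shoulder_halfwidth, s$shoulder_z) +
      (s$upper_arm + s$forearm) * (arm_dir * c(1, 1, 1)),
    wrist_R = c(0, -s$shoulder_halfwidth, s$shoulder_z) +
      (s$upper_arm + s$forearm) * (arm_dir * c(1, -1, 1)),
    knee_L = c(0, s$hip_halfwidth, (s$hip_z + s$ankle_z) / 2),
    knee_R = c(0, -s$hip_halfwidth, (s$hip_z + s$ankle_z) / 2),
    ankle_L = c(0, s$hip_halfwidth, s$ankle_z),
    ankle_R = c(0, -s$hip_halfwidth, s$ankle_z)
  )
  colnames(pose) <- c("x", "y", "z")
  pose
}

# vectorized two-link inverse kinematics: given hip and ankle paths (n x 3)
# and segment lengths, the knee path preserving both lengths exactly;
# the knee bends toward `bend` (default forward, +x)
knee_ik <- function(hip, ankle, l1, l2, bend = c(1, 0, 0)) {
  u <- ankle - hip
  D <- sqrt(rowSums(u^2))
  if (any(D > l1 + l2 + 1e-9)) {
    stop("leg inverse kinematics: hip-ankle distance exceeds leg length",
         call. = FALSE)
  }
  D <- pmin(D, l1 + l2)
  uh <- u / D
  a1 <- (l1^2 - l2^2 + D^2) / (2 * D)
  h <- sqrt(pmax(0, l1^2 - a1^2))
  bend_m <- matrix(bend, nrow(hip), 3, byrow = TRUE)
  w <- bend_m - uh * rowSums(bend_m * uh)
  wn <- sqrt(rowSums(w^2))
  wn[wn < 1e-12] <- 1
  w <- w / wn
  hip + uh * a1 + w * h
}

# arm forward kinematics: straight arm hanging at abduction angle phi from
# vertical, in the frontal (y-z) plane; side = +1 left, -1 right
arm_fk <- function(shoulder, phi, length, side) {
  shoulder + cbind(0, side * sin(phi), -cos(phi)) * length
}

#' Generate a ground-truth skeleton motion sequence
#'
#' Deterministic kinematic template per gesture: sinusoidal arm elevation
#' for `hands_up_down`, whole-body vertical excursion for `jump`, pelvis
#' descent with fixed ankles and knee flexion (exact two-link inverse
#' kinematics) for `squat`, a sagittal split stance with forward-down
#' oscillation for `lunge`, in-place (or constant-speed, see
#' [gesture_spec()]) pelvis translation with alternating leg swings for
#' `walking`, and seeded smooth random sway for `random_movement`. All 16
#' joints are present every frame and every bone length is constant across
#' frames to within floating-point accuracy.
#'
#' @param spec A [gesture_spec()].
#' @return Ground-truth track tibble: `frame_index`, `timestamp_s`, `joint`,
#'   `x_mm`, `y_mm`, `z_mm`.
#' @examples
#' truth <- generate_gesture(gesture_spec("squat", n_frames = 100))
#' @export
generate_gesture <- function(spec) {
  stopifnot(inherits(spec, "gesture_spec"))
  s <- spec$subject
  n <- spec$n_frames
  t <- (seq_len(n) - 1) / spec$frame_rate_hz
  base <- base_pose(s)
  amp <- spec$amplitude
  Tp <- spec$period_s
  cyc <- (1 - cos(2 * pi * t / Tp)) / 2  # 0 -> 1 -> 0, starts at rest

  off <- matrix(0, n, 3)          # rigid offset of torso + arms
  phi <- rep(s$arm_rest_rad, n)   # arm abduction angle
  ankle_L <- matrix(base["ankle_L", ], n, 3, byrow = TRUE)
  ankle_R <- matrix(base["ankle_R", ], n, 3, byrow = TRUE)
  legs_rigid <- FALSE             # translate legs rigidly instead of IK

  if (spec$gesture == "hands_up_down") {
    phi <- s$arm_rest_rad + amp * cyc
    legs_rigid <- TRUE
  } else if (spec$gesture == "jump") {
    off[, 3] <- amp * cyc
    legs_rigid <- TRUE
  } else if (spec$gesture == "squat") {
    off[, 3] <- -amp * cyc
  } else if (spec$gesture == "lunge") {
    stance_drop <- 80
    off[, 1] <- amp * cyc
    off[, 3] <- -stance_drop - 0.5 * amp * cyc
    ankle_L[, 1] <- ankle_L[, 1] + 200
    ankle_R[, 1] <- ankle_R[, 1] - 150
  } else if (spec$gesture == "walking") {
    stance_drop <- 60
    xp <- if (!is.null(spec$speed_mm_s)) spec$speed_mm_s * t
          else amp * sin(2 * pi * t / Tp)
    off[, 1] <- xp
    off[, 3] <- -stance_drop
    step <- 100
    swing <- sin(2 * pi * t / (Tp / 2))
    lift <- 25 * pmax(0, sin(2 * pi * t / (Tp / 2)))^2
    ankle_L[, 1] <- xp + step * swing
    ankle_R[, 1] <- xp - step * swing
    ankle_L[, 3] <- ankle_L[, 3] + lift
    ankle_R[, 3] <- ankle_R[, 3] + 25 * pmax(0, -swing)^2
  } else if (spec$gesture == "random_movement") {
    stance_drop <- 40
    pars <- withr::with_seed(spec$seed, list(
      a = matrix(stats::runif(9, 0.3, 1), 3, 3) * amp,
      Tk = matrix(stats::runif(9, 0.75, 1.25), 3, 3) * Tp,
      ph = matrix(stats::runif(9, 0, 2 * pi), 3, 3)
    ))
    # three independent smooth harmonics per axis, zeroed at t = 0
    for (d in 1:3) {
      for (k in 1:3) {
        off[, d] <- off[, d] + pars$a[k, d] *
          (sin(2 * pi * t / pars$Tk[k, d] + pars$ph[k, d]) -
             sin(pars$ph[k, d]))
      }
    }
    off[, 3] <- off[, 3] * 0.5 - stance_drop
    phi <- s$arm_rest_rad + 0.03 * sin(2 * pi * t / Tp)
  }

  torso <- c("pelvis", "spine_naval", "neck", "head",
             "shoulder_L", "shoulder_R", "hip_L", "hip_R")
  pos <- list()
  for (j in torso) {
    pos[[j]] <- matrix(base[j, ], n, 3, byrow = TRUE) + off
  }
  pos$elbow_L <- arm_fk(pos$shoulder_L, phi, s$upper_arm, +1)
  pos$elbow_R <- arm_fk(pos$shoulder_R, phi, s$upper_arm, -1)
  pos$wrist_L <- arm_fk(pos$shoulder_L, phi, s$upper_arm + s$forearm, +1)
  pos$wrist_R <- arm_fk(pos$shoulder_R, phi, s$upper_arm + s$forearm, -1)
  if (legs_rigid) {
    for (j in c("knee_L", "knee_R", "ankle_L", "ankle_R")) {
      pos[[j]] <- matrix(base[j, ], n, 3, byrow = TRUE) + off
    }
  } else {
    pos$ankle_L <- ankle_L
    pos$ankle_R <- ankle_R
    pos$knee_L <- knee_ik(pos$hip_L, ankle_L, s$thigh, s$shank)
    pos$knee_R <- knee_ik(pos$hip_R, ankle_R, s$thigh, s$shank)
  }

  joints <- joint_names()
  tibble::tibble(
    frame_index = rep(seq_len(n) - 1L, times = length(joints)),
    timestamp_s = rep(t, times = length(joints)),
    joint = rep(joints, each = n),
    x_mm = unlist(lapply(joints, function(j) pos[[j]][, 1]), use.names = FALSE),
    y_mm = unlist(lapply(joints, function(j) pos[[j]][, 2]), use.names = FALSE),
    z_mm = unlist(lapply(joints, function(j) pos[[j]][, 3]), use.names = FALSE)
  ) |>
    dplyr::arrange(.data$frame_index, .data$joint)
}

#' The skeleton's bone (parent-child) segments
#'
#' Used by tests and diagnostics to check bone-length constancy.
#' @return Tibble with columns `from`, `to`.
#' @export
bone_table <- function() {
  tibble::tribble(
    ~from, ~to,
    "pelvis", "spine_naval",
    "spine_naval", "neck",
    "neck", "head",
    "neck", "shoulder_L",
    "neck", "shoulder_R",
    "shoulder_L", "elbow_L",
    "shoulder_R", "elbow_R",
    "elbow_L", "wrist_L",
    "elbow_R", "wrist_R",
    "pelvis", "hip_L",
    "pelvis", "hip_R",
    "hip_L", "knee_L",
    "hip_R", "knee_R",
    "knee_L", "ankle_L",
    "knee_R", "ankle_R"
  )
}

#' Multi-sensor capture rig
#'
#' Sensors are placed on a circle around the capture area, looking at the
#' subject. The pose of each sensor is the rigid transform mapping its
#' camera coordinates (z forward toward the subject, x right, y down) into
#' the global frame.
#'
#' @param n_sensors Number of sensors (>= 1).
#' @param distance_mm Radius of the sensor circle.
#' @param height_mm Mounting height of the sensor origins.
#' @param angles_deg Azimuth of each sensor (0 = in front of the subject,
#'   who faces +x). Default: evenly spread avoiding the exact front
#'   (`45, 135, 225, 315` for four sensors).
#' @param reference_sensor Optional id of a designated best-view sensor.
#' @return Tibble with columns `sensor_id`, `pose` (list of
#'   [rigid_transform()]), `azimuth_deg`; attribute `reference_sensor`.
#' @export
sensor_rig <- function(n_sensors = 4, distance_mm = 2500, height_mm = 800,
                       angles_deg = NULL, reference_sensor = NULL) {
  stopifnot(n_sensors >= 1)
  if (is.null(angles_deg)) {
    angles_deg <- 45 + 360 * (seq_len(n_sensors) - 1) / n_sensors
  }
  stopifnot(length(angles_deg) == n_sensors)
  target <- c(0, 0, 1000)
  poses <- lapply(angles_deg, function(a) {
    th <- a * pi / 180
    origin <- c(distance_mm * cos(th), distance_mm * sin(th), height_mm)
    zc <- target - origin
    zc <- zc / sqrt(sum(zc^2))
    up <- c(0, 0, 1)
    xc <- cross3(zc, up)
    xc <- xc / sqrt(sum(xc^2))
    yc <- cross3(zc, xc)
    rigid_transform(cbind(xc, yc, zc), origin, check = FALSE)
  })
  out <- tibble::tibble(
    sensor_id = sprintf("s%d", seq_len(n_sensors)),
    pose = poses,
    azimuth_deg = angles_deg
  )
  attr(out, "reference_sensor") <- reference_sensor
  out
}

#' Per-sensor corruption model
#'
#' Emulates the error structure of markerless body tracking: isotropic
#' Gaussian jitter on every observation (inflated for occluded joints, which
#' the tracker estimates rather than tracks), large occlusion-driven outlier
#' displacements, per-pair left/right label swaps (swapped joints are
#' demoted to `low` confidence, matching the phenomenology that misoriented
#' joints are occlusion-time estimates), and dropouts (confidence `none`).
#' A joint is occluded for a sensor when the angle between the subject's
#' facing direction (+x) and the joint-to-sensor ray exceeds
#' `occlusion_angle_deg`.
#'
#' @param jitter_sigma_mm Per-axis Gaussian jitter, visible joints.
#' @param occluded_jitter_sigma_mm Per-axis jitter for occluded joints.
#' @param outlier_prob Probability that an occluded joint receives an
#'   outlier displacement (uniform direction, half-normal magnitude with
#'   scale `outlier_scale_mm`).
#' @param outlier_scale_mm Scale of the outlier displacement magnitude.
#' @param swap_prob Per mirrored pair, per frame, per sensor swap
#'   probability.
#' @param dropout_prob Per joint observation dropout probability.
#' @param occlusion_angle_deg Facing-angle threshold beyond which a joint is
#'   occluded for a sensor (180 disables occlusion).
#' @param seed Integer seed; all corruption is reproducible given it.
#' @return A `noise_model` object.
#' @export
noise_model <- function(jitter_sigma_mm = 5, occluded_jitter_sigma_mm = 15,
                        outlier_prob = 0.15, outlier_scale_mm = 300,
                        swap_prob = 0.02, dropout_prob = 0.02,
                        occlusion_angle_deg = 90, seed = 1L) {
  stopifnot(jitter_sigma_mm >= 0, occluded_jitter_sigma_mm >= 0,
            outlier_prob >= 0, outlier_prob <= 1,
            swap_prob >= 0, swap_prob <= 1,
            dropout_prob >= 0, dropout_prob <= 1)
  structure(list(
    jitter_sigma_mm = jitter_sigma_mm,
    occluded_jitter_sigma_mm = occluded_jitter_sigma_mm,
    outlier_prob = outlier_prob, outlier_scale_mm = outlier_scale_mm,
    swap_prob = swap_prob, dropout_prob = dropout_prob,
    occlusion_angle_deg = occlusion_angle_deg, seed = as.integer(seed)
  ), class = "noise_model")
}

#' Corrupt a ground-truth sequence into per-sensor observation streams
#'
#' For every sensor, frame and joint: decides occlusion from the rig
#' geometry, applies the [noise_model()] corruptions, and assigns
#' confidences (`medium` for visible, `low` for occluded or swapped, `none`
#' for dropouts, whose positions are `NA`).
#'
#' @param truth Ground-truth track from [generate_gesture()].
#' @param rig A [sensor_rig()].
#' @param noise A [noise_model()].
#' @param frame `"global"` (default) emits calibrated streams in the global
#'   frame; `"sensor"` transforms each stream into its sensor's own
#'   coordinates (to be re-calibrated downstream).
#' @return Skeleton stream tibble covering all sensors.
#' @export
observe <- function(truth, rig, noise, frame = c("global", "sensor")) {
  frame <- match.arg(frame)
  stopifnot(inherits(noise, "noise_model"))
  if (nrow(rig) < 1) stop("empty sensor rig", call. = FALSE)
  truth <- dplyr::arrange(tibble::as_tibble(truth),
                          .data$frame_index, .data$joint)
  nt <- nrow(truth)
  cos_th <- cos(noise$occlusion_angle_deg * pi / 180)

  streams <- withr::with_seed(noise$seed, {
    lapply(seq_len(nrow(rig)), function(i) {
      obs <- truth
      obs$sensor_id <- rig$sensor_id[i]
      pos <- as.matrix(obs[, c("x_mm", "y_mm", "z_mm")])
      spos <- rig$pose[[i]]$translation
      ray <- -sweep(pos, 2, spos)            # joint -> sensor
      occluded <- (ray[, 1] / sqrt(rowSums(ray^2))) < cos_th
      conf <- ifelse(occluded, "low", "medium")
      # occlusion-driven outliers
      is_out <- occluded & stats::runif(nt) < noise$outlier_prob
      n_out <- sum(is_out)
      if (n_out > 0) {
        dir <- r_unit_sphere(n_out)
        mag <- abs(stats::rnorm(n_out, 0, noise$outlier_scale_mm))
        pos[is_out, ] <- pos[is_out, ] + dir * mag
      }
      # jitter (inflated when occluded)
      sd_row <- ifelse(occluded, noise$occluded_jitter_sigma_mm,
                       noise$jitter_sigma_mm)
      pos <- pos + matrix(stats::rnorm(3 * nt), nt, 3) * sd_row
      # left/right swaps, demoting the pair to low confidence
      pairs <- mirror_pairs()
      for (p in seq_len(nrow(pairs))) {
        ir <- which(obs$joint == pairs$right[p])
        il <- which(obs$joint == pairs$left[p])
        sw <- stats::runif(length(ir)) < noise$swap_prob
        if (any(sw)) {
          tmp <- pos[ir[sw], , drop = FALSE]
          pos[ir[sw], ] <- pos[il[sw], , drop = FALSE]
          pos[il[sw], ] <- tmp
          conf[ir[sw]] <- "low"
          conf[il[sw]] <- "low"
        }
      }
      # dropouts
      drop <- stats::runif(nt) < noise$dropout_prob
      conf[drop] <- "none"
      pos[drop, ] <- NA_real_
      if (frame == "sensor") {
        inv <- rt_inverse(rig$pose[[i]])
        ok <- !drop
        pos[ok, ] <- rt_apply(inv, pos[ok, , drop = FALSE])
      }
      obs$x_mm <- pos[, 1]
      obs$y_mm <- pos[, 2]
      obs$z_mm <- pos[, 3]
      obs$confidence <- conf
      obs
    })
  })
  dplyr::bind_rows(streams)
}

#' Write a complete synthetic benchmark to disk
#'
#' Generates the ground truth and per-sensor corrupted streams and writes
#' them as CSV together with a JSON manifest recording every parameter and
#' seed, so the benchmark can be re-created bit-for-bit.
#'
#' @param spec A [gesture_spec()].
#' @param rig A [sensor_rig()].
#' @param noise A [noise_model()].
#' @param dir Output directory (created if needed).
#' @param frame Passed to [observe()].
#' @return (Invisibly) list with `streams` (per-sensor file paths), `truth`,
#'   `manifest`.
#' @export
make_benchmark <- function(spec, rig, noise, dir, frame = "global") {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", dir, call. = FALSE)
  }
  truth <- generate_gesture(spec)
  stream <- observe(truth, rig, noise, frame = frame)
  truth_path <- file.path(dir, "truth.csv")
  readr::write_csv(truth, truth_path)
  paths <- vapply(rig$sensor_id, function(sid) {
    p <- file.path(dir, paste0("stream_", sid, ".csv"))
    write_skeleton_stream(stream[stream$sensor_id == sid, ], p)
    p
  }, character(1))
  manifest <- list(
    generator = "skelmerge make_benchmark",
    gesture = unclass(spec),
    rig = list(sensor_id = rig$sensor_id, azimuth_deg = rig$azimuth_deg,
               poses = lapply(rig$pose, function(p)
                 list(rotation = as.numeric(t(p$rotation)),
                      translation_mm = p$translation))),
    noise = unclass(noise),
    frame = frame,
    files = list(truth = basename(truth_path),
                 streams = as.list(basename(paths)))
  )
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(streams = unname(paths), truth = truth_path,
                 manifest = manifest_path))
}
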