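#' Kalman tracking configuration
#'
#' Per-joint constant-position Kalman filter with identity transition and
#' measurement matrices and isotropic noise: process-noise variance `q`
#' (default 0.01) and measurement-noise variance `r` (default 1.0), the
#' values used throughout the pipeline.
#'
#' @param q Process-noise variance (> 0).
#' @param r Measurement-noise variance (> 0).
#' @export
kalman_config <- function(q = 0.01, r = 1.0) {
  stopifnot(q > 0, r > 0)
  structure(list(q = q, r = r), class = "kalman_config")
}

#' Fusion pipeline configuration
#'
#' Selects the merging variant and its parameters:
#' * `A1` — plain per-joint averaging of all sensor candidates;
#' * `A2` — `A1` preceded by left/right misorientation correction;
#' * `A3` — misorientation correction, then DBSCAN largest-cluster merging
#'   with the cross-sensor reference position as an auxiliary candidate;
#' * `A4` — `A3` plus the previous merged position as a one-frame smoothing
#'   candidate;
#' * `A5` — `A4` plus per-joint Kalman tracking (the full pipeline).
#'
#' @param variant One of `"A1"`, `"A2"`, `"A3"`, `"A4"`, `"A5"`.
#' @param eps_mm DBSCAN searching area (neighborhood radius), millimeters.
#'   The best-performing value is 100 mm (10 cm).
#' @param min_neighbors DBSCAN minimum neighborhood size `N_c` (fixed to 1 in
#'   the reference pipeline; a point's neighborhood includes itself).
#' @param use_reference_candidate Include the confidence-weighted reference
#'   position as an auxiliary clustering candidate.
#' @param use_previous_candidate Include the previous merged position as an
#'   auxiliary clustering candidate; defaults to the variant's convention
#'   (`TRUE` for A4/A5).
#' @param arrange Run misorientation correction; defaults to the variant's
#'   convention (all variants except A1).
#' @param kalman A [kalman_config()].
#' @param max_predict_frames After this many consecutive frames with no
#'   measurement a joint is reported `missing` instead of extrapolated.
#' @param include_spine_chest Use the 17-joint skeleton.
#' @return A `fusion_config` object.
#' @export
fusion_config <- function(variant = c("A5", "A1", "A2", "A3", "A4"),
                          eps_mm = 100, min_neighbors = 1L,
                          use_reference_candidate = TRUE,
                          use_previous_candidate = NULL,
                          arrange = NULL,
                          kalman = kalman_config(),
                          max_predict_frames = 30L,
                          include_spine_chest = FALSE) {
  variant <- match.arg(variant)
  stopifnot(eps_mm > 0, min_neighbors >= 1)
  defaults <- list(
    A1 = list(arrange = FALSE, dbscan = FALSE, prev = FALSE, kalman = FALSE),
    A2 = list(arrange = TRUE,  dbscan = FALSE, prev = FALSE, kalman = FALSE),
    A3 = list(arrange = TRUE,  dbscan = TRUE,  prev = FALSE, kalman = FALSE),
    A4 = list(arrange = TRUE,  dbscan = TRUE,  prev = TRUE,  kalman = FALSE),
    A5 = list(arrange = TRUE,  dbscan = TRUE,  prev = TRUE,  kalman = TRUE)
  )[[variant]]
  structure(list(
    variant = variant,
    eps_mm = eps_mm,
    min_neighbors = as.integer(min_neighbors),
    use_reference_candidate = isTRUE(use_reference_candidate),
    use_previous_candidate = if (is.null(use_previous_candidate))
      defaults$prev else isTRUE(use_previous_candidate),
    arrange = if (is.null(arrange)) defaults$arrange else isTRUE(arrange),
    use_dbscan = defaults$dbscan,
    use_kalman = defaults$kalman,
    kalman = kalman,
    max_predict_frames = as.integer(max_predict_frames),
    include_spine_chest = isTRUE(include_spine_chest)
  ), class = "fusion_config")
}

#' @export
print.fusion_config <- function(x, ...) {
  cat("<fusion_config> variant", x$variant,
      "| eps", x$eps_mm, "mm | Nc", x$min_neighbors,
      "| arrange", x$arrange,
      "| ref", x$use_reference_candidate,
      "| prev", x$use_previous_candidate,
      "| kalman", x$use_kalman,
      sprintf("(q=%g, r=%g)\n", x$kalman$q, x$kalman$r))
  invisible(x)
}

engine_config <- function(config) {
  list(arrange = config$arrange, use_dbscan = config$use_dbscan,
       use_reference = config$use_reference_candidate,
       use_previous = config$use_previous_candidate,
       use_kalman = config$use_kalman, eps_mm = config$eps_mm,
       min_neighbors = config$min_neighbors,
       q = config$kalman$q, r = config$kalman$r,
       max_predict = config$max_predict_frames)
}

conf_code <- function(confidence) {
  c(medium = 2L, low = 1L, none = 0L)[confidence]
}

# encode a stream for the C++ engine: 0-based sensor/joint codes, rows with
# confidence "none" dropped, sorted by frame_index (stable)
encode_stream <- function(stream, include_spine_chest = FALSE) {
  joints <- joint_names(include_spine_chest)
  keep <- which(stream$confidence != "none")
  sub <- stream[keep, ]
  ord <- order(sub$frame_index)
  sub <- sub[ord, ]
  sensors <- sort(unique(stream$sensor_id))
  tbl <- joint_table(include_spine_chest)
  mirror <- match(tbl$mirror, tbl$joint) - 1L
  mirror[is.na(mirror)] <- -1L
  list(
    frame = as.integer(sub$frame_index),
    sensor = match(sub$sensor_id, sensors) - 1L,
    joint = match(sub$joint, joints) - 1L,
    pos = as.matrix(sub[, c("x_mm", "y_mm", "z_mm")]),
    conf = unname(conf_code(sub$confidence)),
    row_idx = keep[ord],
    sensors = sensors,
    joints = joints,
    mirror = mirror,
    is_right = as.integer(grepl("_R$", joints))
  )
}

status_levels <- c("missing", "merged", "predicted_only")

# stream-order check: within each sensor the frame indices must be
# non-decreasing as given
check_stream_order <- function(stream) {
  bad <- stream |>
    dplyr::group_by(.data$sensor_id) |>
    dplyr::summarise(ok = !is.unsorted(.data$frame_index)) |>
    dplyr::filter(!.data$ok)
  if (nrow(bad) > 0) {
    stop("stream-order error: non-monotone frame indices for sensor(s) ",
         paste(bad$sensor_id, collapse = ", "), call. = FALSE)
  }
  invisible(stream)
}

#' Cross-sensor reference position of a joint
#'
#' The mean of the candidate positions with `medium` confidence; when no
#' candidate is `medium`, the mean of the `low`-confidence candidates; `NULL`
#' when every candidate has confidence `none` (or there are no candidates).
#'
#' @param positions n x 3 matrix of candidate positions (mm).
#' @param confidence Character vector of length n (`medium`/`low`/`none`).
#' @return Length-3 numeric vector, or `NULL`.
#' @export
reference_position <- function(positions, confidence) {
  positions <- matrix(as.numeric(as.matrix(positions)), ncol = 3)
  stopifnot(nrow(positions) == length(confidence))
  for (level in c("medium", "low")) {
    idx <- which(confidence == level)
    if (length(idx) > 0) return(colMeans(positions[idx, , drop = FALSE]))
  }
  NULL
}

#' Misorientation check for one left/right joint pair
#'
#' Compares one sensor's right/left positions of a paired joint against the
#' cross-sensor reference position of the right joint:
#' `d_correct = ||ref_r - target_r||`, `d_wrong = ||ref_r - target_l||`
#' (Euclidean, mm). The pair is flagged as swapped when
#' `d_correct > d_wrong`; ties are conservatively not swapped.
#'
#' @param ref_r Reference position of the right joint (length 3, mm).
#' @param target_r,target_l The sensor's right/left positions (length 3, mm).
#' @param ref_l Optional reference position of the left joint (recorded in
#'   the result, not used by the rule).
#' @return List with `ref_right`, `ref_left`, `d_correct`, `d_wrong`,
#'   `swapped`.
#' @export
check_pair <- function(ref_r, target_r, target_l, ref_l = NULL) {
  stopifnot(all(is.finite(ref_r)), all(is.finite(target_r)),
            all(is.finite(target_l)))
  d_correct <- sqrt(sum((ref_r - target_r)^2))
  d_wrong <- sqrt(sum((ref_r - target_l)^2))
  list(ref_right = ref_r, ref_left = ref_l,
       d_correct = d_correct, d_wrong = d_wrong,
       swapped = d_correct > d_wrong)
}

#' Correct left/right misoriented joint labels across sensors
#'
#' For every mirrored joint pair and every sensor that observes both members
#' (confidence not `none`), the sensor's pair is checked against the
#' cross-sensor reference position ([check_pair()]) and its left/right labels
#' are exchanged when flagged. Observations of sensors missing one pair
#' member, and all midline joints, are left untouched. The input may contain
#' any number of frames; frames are corrected independently.
#'
#' @param stream Skeleton stream tibble (see [validate_stream()]).
#' @param include_spine_chest Use the 17-joint skeleton.
#' @return The corrected stream with an added logical column `swapped`.
#' @export
arrange_frame <- function(stream, include_spine_chest = FALSE) {
  stream <- validate_stream(stream)
  enc <- encode_stream(stream, include_spine_chest)
  out <- stream
  out$swapped <- FALSE
  if (length(enc$frame) == 0) return(out)
  res <- cpp_arrange_stream(enc$frame, enc$sensor, enc$joint, enc$pos,
                            enc$conf, length(enc$sensors),
                            length(enc$joints), enc$mirror, enc$is_right)
  out$x_mm[enc$row_idx] <- res$pos[, 1]
  out$y_mm[enc$row_idx] <- res$pos[, 2]
  out$z_mm[enc$row_idx] <- res$pos[, 3]
  out$confidence[enc$row_idx] <- names(conf_code(confidence_levels()))[
    match(res$conf, conf_code(confidence_levels()))]
  out$swapped[enc$row_idx] <- res$swapped
  out
}

#' DBSCAN clustering of joint candidates
#'
#' Density-based clustering with searching area `eps_mm` and minimum
#' neighborhood size `min_neighbors`. The neighbor test is the closed
#' Euclidean inequality `distance <= eps_mm` and a point's neighborhood
#' includes the point itself, so with `min_neighbors = 1` every point is a
#' core point, no point is labeled noise, and the clusters are exactly the
#' connected components of the eps-neighborhood graph.
#'
#' @param points n x 3 matrix of positions (mm).
#' @param eps_mm Neighborhood radius (> 0), mm.
#' @param min_neighbors Minimum neighborhood size (>= 1) for a core point.
#' @return List with `labels` (integer per point: 0 = noise, otherwise a
#'   contiguous cluster id 1..k) and `k` (number of clusters).
#' @examples
#' dbscan_cluster(cbind(c(0, 50, 200), 0, 0), eps_mm = 100)
#' @export
dbscan_cluster <- function(points, eps_mm, min_neighbors = 1L) {
  stopifnot(eps_mm > 0, min_neighbors >= 1)
  points <- matrix(as.numeric(as.matrix(points)), ncol = 3)
  if (nrow(points) == 0) return(list(labels = integer(0), k = 0L))
  labels <- cpp_dbscan(points, eps_mm, as.integer(min_neighbors))
  list(labels = labels, k = max(0L, labels))
}

#' Merge one joint's sensor candidates into a single position
#'
#' Clusters the sensor candidates together with the auxiliary candidates
#' (the cross-sensor `reference` position and the `previous` merged
#' position, when given) by DBSCAN, selects the cluster with the most
#' members, and returns the centroid of the winning cluster's *sensor*
#' candidates only — auxiliary candidates anchor the cluster choice but are
#' excluded from the centroid so the merged position stays inside the range
#' of actually observed joints. If the winning cluster contains no sensor
#' candidate (or there are no candidates at all), the previous position is
#' carried forward with status `predicted_only`; with no previous position
#' the status is `missing`.
#'
#' @param candidates n x 3 matrix of sensor candidate positions (mm).
#' @param reference Optional length-3 reference position.
#' @param previous Optional length-3 previous merged position.
#' @param eps_mm,min_neighbors DBSCAN parameters (see [dbscan_cluster()]).
#' @return List with `position` (length 3 or `NA`), `n_contributing` and
#'   `status` (`"merged"`, `"predicted_only"` or `"missing"`).
#' @export
merge_joint <- function(candidates, reference = NULL, previous = NULL,
                        eps_mm = 100, min_neighbors = 1L) {
  candidates <- matrix(as.numeric(as.matrix(candidates)), ncol = 3)
  res <- cpp_merge_joint(candidates,
                         if (is.null(reference)) numeric(0)
                         else as.numeric(reference),
                         if (is.null(previous)) numeric(0)
                         else as.numeric(previous),
                         eps_mm, as.integer(min_neighbors))
  list(position = res$position, n_contributing = res$n_contributing,
       status = status_levels[res$status + 1L])
}

#' One step of the per-joint Kalman tracker
#'
#' Constant-position linear Kalman filter with identity transition and
#' measurement matrices and isotropic noise (see [kalman_config()]).
#' Prediction: `x_pred = x_post`, `P_pred = P_post + q I`. With a
#' measurement `z`: gain `K = P_pred (P_pred + r I)^-1`,
#' `x_post = x_pred + K (z - x_pred)`, `P_post = (I - K) P_pred`; without a
#' measurement the prediction is carried forward. The returned `tracked`
#' position is the prediction; at initialization it equals the first
#' measurement (with `P_post = I`).
#'
#' @param state A tracker state from a previous call, or `NULL` to
#'   initialize.
#' @param measurement Length-3 measurement (mm), or `NULL` when the joint was
#'   not merged this frame.
#' @param config A [kalman_config()].
#' @return List with `state` (fields `x_post`, `p_post`, `x_pred`, `p_pred`,
#'   `last_gain`, `initialized`) and `tracked` (length-3 position).
#' @export
kalman_step <- function(state, measurement, config = kalman_config()) {
  I3 <- diag(3)
  if (is.null(state) || !isTRUE(state$initialized)) {
    if (is.null(measurement)) {
      stop("cannot track: tracker not initialized and no measurement",
           call. = FALSE)
    }
    measurement <- as.numeric(measurement)
    state <- list(x_post = measurement, p_post = I3,
                  x_pred = measurement, p_pred = I3,
                  last_gain = matrix(NA_real_, 3, 3), initialized = TRUE)
    return(list(state = state, tracked = measurement))
  }
  x_pred <- state$x_post
  p_pred <- state$p_post + config$q * I3
  tracked <- x_pred
  if (!is.null(measurement)) {
    measurement <- as.numeric(measurement)
    K <- p_pred %*% solve(p_pred + config$r * I3)
    x_post <- x_pred + as.numeric(K %*% (measurement - x_pred))
    p_post <- (I3 - K) %*% p_pred
  } else {
    K <- state$last_gain
    x_post <- x_pred
    p_post <- p_pred
  }
  list(state = list(x_post = x_post, p_post = p_post,
                    x_pred = x_pred, p_pred = p_pred,
                    last_gain = K, initialized = TRUE),
       tracked = tracked)
}

decode_track <- function(res, joints) {
  tibble::tibble(
    frame_index = res$frame_index,
    joint = joints[res$joint + 1L],
    x_mm = res$pos[, 1],
    y_mm = res$pos[, 2],
    z_mm = res$pos[, 3],
    status = status_levels[res$status + 1L],
    n_contributing = res$n_contributing
  )
}

#' Fuse the skeleton observations of one time step
#'
#' Runs the configured pipeline (arrangement, merging, tracking) on the
#' frames of a single `frame_index` shared by several sensors, optionally
#' continuing from the state returned by a previous call. [fuse_sequence()]
#' is the equivalent stateful pass over a whole stream.
#'
#' @param stream Skeleton stream tibble containing exactly one `frame_index`.
#' @param config A [fusion_config()].
#' @param state Engine state from a previous call (or `NULL` to start).
#' @return List with `merged` (one-row-per-joint tibble: position, `status`,
#'   `n_contributing`) and `state`.
#' @export
fuse_frame <- function(stream, config = fusion_config(), state = NULL) {
  stream <- validate_stream(stream)
  if (length(unique(stream$frame_index)) > 1) {
    stop("fuse_frame expects a single frame_index; use fuse_sequence()",
         call. = FALSE)
  }
  if (nrow(stream) == 0) stop("empty frame list: no skeleton to fuse",
                              call. = FALSE)
  enc <- encode_stream(stream, config$include_spine_chest)
  res <- cpp_fuse_stream(enc$frame, enc$sensor, enc$joint, enc$pos, enc$conf,
                         length(enc$sensors), length(enc$joints), enc$mirror,
                         enc$is_right, engine_config(config),
                         if (is.null(state)) list() else state)
  list(merged = decode_track(res, enc$joints), state = res$state)
}

#' Fuse a multi-sensor skeleton stream into one merged track
#'
#' Stateful left-to-right pass over the synchronized frames of a multi-sensor
#' stream: per frame, misorientation arrangement, per-joint DBSCAN merging
#' with auxiliary candidates, and Kalman tracking, as selected by the
#' variant in `config`. Frame indices missing from the input (all-sensor
#' dropouts) are emitted as `predicted_only` (or `missing` once the
#' sustained-dropout cutoff is exceeded). Trackers initialize at each
#' joint's first merged measurement.
#'
#' @param stream Skeleton stream tibble with observations from all sensors
#'   (see [validate_stream()]), synchronized on `frame_index`.
#' @param config A [fusion_config()].
#' @return A merged track tibble: `frame_index`, `joint`, `x_mm`, `y_mm`,
#'   `z_mm`, `status` (`merged`/`predicted_only`/`missing`),
#'   `n_contributing`.
#' @examples
#' truth <- generate_gesture(gesture_spec("squat", n_frames = 30))
#' stream <- observe(truth, sensor_rig(4), noise_model(seed = 1))
#' merged <- fuse_sequence(stream, fusion_config("A5"))
#' head(merged)
#' @export
fuse_sequence <- function(stream, config = fusion_config()) {
  stream <- validate_stream(stream)
  if (nrow(stream) == 0) stop("empty stream: no skeleton to fuse",
                              call. = FALSE)
  check_stream_order(stream)
  enc <- encode_stream(stream, config$include_spine_chest)
  res <- cpp_fuse_stream(enc$frame, enc$sensor, enc$joint, enc$pos, enc$conf,
                         length(enc$sensors), length(enc$joints), enc$mirror,
                         enc$is_right, engine_config(config), list())
  decode_track(res, enc$joints)
}
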