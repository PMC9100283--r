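#' Skeleton topology: joints, regions, left/right pairs
#'
#' The tracked skeleton uses 16 joint centers: eight torso joints (pelvis,
#' spine_naval, neck, head, both shoulders, both hips), four upper-limb joints
#' (elbows, wrists) and four lower-limb joints (knees, ankles). An optional
#' 17th joint, `spine_chest`, can be enabled for trackers that report it
#' separately from `spine_naval`; it belongs to the torso and has no mirror
#' partner.
#'
#' @param include_spine_chest Add the optional `spine_chest` torso joint.
#' @return `joint_table()` returns a tibble with columns `joint`, `region`
#'   (`torso`, `upper_limb`, `lower_limb`) and `mirror` (the contralateral
#'   joint name, or `NA` for midline joints).
#' @examples
#' joint_table()
#' mirror_partner("elbow_L")
#' region_of(c("hip_L", "wrist_R"))
#' @export
joint_table <- function(include_spine_chest = FALSE) {
  tbl <- tibble::tribble(
    ~joint,        ~region,      ~mirror,
    "pelvis",      "torso",      NA_character_,
    "spine_naval", "torso",      NA_character_,
    "neck",        "torso",      NA_character_,
    "head",        "torso",      NA_character_,
    "shoulder_L",  "torso",      "shoulder_R",
    "shoulder_R",  "torso",      "shoulder_L",
    "hip_L",       "torso",      "hip_R",
    "hip_R",       "torso",      "hip_L",
    "elbow_L",     "upper_limb", "elbow_R",
    "elbow_R",     "upper_limb", "elbow_L",
    "wrist_L",     "upper_limb", "wrist_R",
    "wrist_R",     "upper_limb", "wrist_L",
    "knee_L",      "lower_limb", "knee_R",
    "knee_R",      "lower_limb", "knee_L",
    "ankle_L",     "lower_limb", "ankle_R",
    "ankle_R",     "lower_limb", "ankle_L"
  )
  if (include_spine_chest) {
    tbl <- dplyr::add_row(tbl,
      joint = "spine_chest", region = "torso", mirror = NA_character_,
      .after = 2
    )
  }
  tbl
}

#' @rdname joint_table
#' @export
joint_names <- function(include_spine_chest = FALSE) {
  joint_table(include_spine_chest)$joint
}

#' Confidence levels of tracked joints
#'
#' Body trackers report each joint with one of three confidence levels:
#' `medium` (tracked), `low` (estimated, e.g. under occlusion) and `none`
#' (outside the field of view). The levels are totally ordered
#' `medium > low > none`.
#'
#' @return Character vector of the levels in decreasing order of trust.
#' @export
confidence_levels <- function() c("medium", "low", "none")

assert_joints <- function(j, include_spine_chest = FALSE) {
  bad <- setdiff(unique(j), joint_names(include_spine_chest))
  if (length(bad) > 0) {
    stop("unknown joint name(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(j)
}

#' @rdname joint_table
#' @param j Character vector of joint names.
#' @export
mirror_partner <- function(j, include_spine_chest = FALSE) {
  assert_joints(j, include_spine_chest)
  tbl <- joint_table(include_spine_chest)
  tbl$mirror[match(j, tbl$joint)]
}

#' @rdname joint_table
#' @export
region_of <- function(j, include_spine_chest = FALSE) {
  assert_joints(j, include_spine_chest)
  tbl <- joint_table(include_spine_chest)
  tbl$region[match(j, tbl$joint)]
}

#' The paired (left/right) joints subject to misorientation correction
#'
#' Returns one row per mirrored pair: the limb, hip and shoulder joints.
#'
#' @return Tibble with columns `right` and `left`.
#' @export
mirror_pairs <- function(include_spine_chest = FALSE) {
  tbl <- joint_table(include_spine_chest)
  paired <- tbl[!is.na(tbl$mirror) & grepl("_R$", tbl$joint), ]
  tibble::tibble(right = paired$joint, left = paired$mirror)
}

#' Validate a skeleton stream table
#'
#' A skeleton stream is a tibble with one row per (frame, sensor, joint)
#' observation: columns `frame_index`, `sensor_id`, `joint`, `x_mm`, `y_mm`,
#' `z_mm`, `confidence` (and optionally `timestamp_s`). Positions must be
#' finite whenever `confidence != "none"`; `none` rows may carry `NA`
#' positions.
#'
#' @param stream A data frame in the stream layout.
#' @return The validated stream as a tibble (invisibly unchanged rows).
#' @export
validate_stream <- function(stream) {
  required <- c("frame_index", "sensor_id", "joint", "x_mm", "y_mm", "z_mm",
                "confidence")
  missing <- setdiff(required, names(stream))
  if (length(missing) > 0) {
    stop("stream is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad_conf <- which(!stream$confidence %in% confidence_levels())
  if (length(bad_conf) > 0) {
    stop("invalid confidence value '", stream$confidence[bad_conf[1]],
         "' at row ", bad_conf[1], call. = FALSE)
  }
  assert_joints(stream$joint, include_spine_chest = TRUE)
  pos <- as.matrix(stream[, c("x_mm", "y_mm", "z_mm")])
  live <- stream$confidence != "none"
  bad_pos <- which(live & !matrixStats_all_finite(pos))
  if (length(bad_pos) > 0) {
    stop("non-finite position with confidence != 'none' at row ", bad_pos[1],
         call. = FALSE)
  }
  if (any(stream$frame_index < 0)) stop("negative frame_index", call. = FALSE)
  dup <- duplicated(stream[, c("frame_index", "sensor_id", "joint")])
  if (any(dup)) {
    stop("duplicate observation for (frame_index, sensor_id, joint) at row ",
         which(dup)[1], call. = FALSE)
  }
  tibble::as_tibble(stream)
}

# rowwise all-finite over a 3-column matrix
matrixStats_all_finite <- function(pos) {
  is.finite(pos[, 1]) & is.finite(pos[, 2]) & is.finite(pos[, 3])
}
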