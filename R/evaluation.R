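#' Per-joint Euclidean position errors between two tracks
#'
#' Joins the two tracks on (`frame_index`, `joint`) and computes the
#' Euclidean distance in millimeters. Observations present in only one
#' track, or non-finite in either, are excluded pairwise; the exclusion
#' count is attached as attribute `n_excluded`.
#'
#' @param merged A merged track (from [fuse_sequence()]) or any table with
#'   `frame_index`, `joint`, `x_mm`, `y_mm`, `z_mm`.
#' @param truth The reference track in the same coordinate frame (simulated
#'   ground truth or a best-view skeleton stream).
#' @return Tibble of class `joint_errors`: `frame_index`, `joint`, `region`,
#'   `error_mm`.
#' @export
joint_errors <- function(merged, truth) {
  pick <- function(x, suffix) {
    x <- tibble::as_tibble(x)[, c("frame_index", "joint",
                                  "x_mm", "y_mm", "z_mm")]
    names(x)[3:5] <- paste0(c("x", "y", "z"), suffix)
    x
  }
  joined <- dplyr::inner_join(pick(merged, "_a"), pick(truth, "_b"),
                              by = c("frame_index", "joint"))
  if (nrow(joined) == 0) {
    stop("empty overlap: the tracks share no (frame_index, joint) pairs",
         call. = FALSE)
  }
  finite <- is.finite(joined$x_a) & is.finite(joined$y_a) &
    is.finite(joined$z_a) & is.finite(joined$x_b) &
    is.finite(joined$y_b) & is.finite(joined$z_b)
  n_union <- length(unique(paste(merged$frame_index, merged$joint))) +
    length(unique(paste(truth$frame_index, truth$joint))) -
    nrow(joined)
  out <- joined[finite, ]
  res <- tibble::tibble(
    frame_index = out$frame_index,
    joint = out$joint,
    region = region_of(out$joint, include_spine_chest = TRUE),
    error_mm = sqrt((out$x_a - out$x_b)^2 + (out$y_a - out$y_b)^2 +
                      (out$z_a - out$z_b)^2)
  ) |>
    dplyr::arrange(.data$frame_index, .data$joint)
  # pairs present in either track but not scored (missing or non-finite)
  attr(res, "n_excluded") <- n_union - nrow(res)
  class(res) <- c("joint_errors", class(res))
  res
}

#' Aggregate joint errors by body region
#'
#' Pools the per-frame, per-joint errors within each body region (torso,
#' upper limb, lower limb) and reports the average error (AE), its standard
#' deviation (STD; population formula by default) and the RMSE, all in
#' millimeters.
#'
#' @param errors A `joint_errors` table from [joint_errors()].
#' @param std `"population"` (n denominator, default) or `"sample"` (n - 1).
#' @return Tibble of class `region_error_summary`: `region`, `ae_mm`,
#'   `std_mm`, `rmse_mm`, `n`.
#' @export
region_summary <- function(errors, std = c("population", "sample")) {
  std <- match.arg(std)
  out <- errors |>
    dplyr::group_by(region = factor(.data$region, levels = c(
      "torso", "upper_limb", "lower_limb"))) |>
    dplyr::summarise(
      ae_mm = mean(.data$error_mm),
      std_mm = if (std == "population") {
        sqrt(mean((.data$error_mm - mean(.data$error_mm))^2))
      } else {
        stats::sd(.data$error_mm)
      },
      rmse_mm = sqrt(mean(.data$error_mm^2)),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(region = as.character(.data$region))
  class(out) <- c("region_error_summary", class(out))
  out
}

# rebuild a config with a different variant / eps, keeping shared knobs
config_with <- function(config, variant = config$variant,
                        eps_mm = config$eps_mm) {
  fusion_config(variant = variant, eps_mm = eps_mm,
                min_neighbors = config$min_neighbors,
                use_reference_candidate = config$use_reference_candidate,
                kalman = config$kalman,
                max_predict_frames = config$max_predict_frames,
                include_spine_chest = config$include_spine_chest)
}

#' Sweep the DBSCAN searching area
#'
#' Re-runs the fusion pipeline on identical inputs for each value of the
#' searching area and tabulates the region error summaries.
#'
#' @param stream Multi-sensor skeleton stream.
#' @param truth Reference track.
#' @param config Base [fusion_config()]; only `eps_mm` is varied.
#' @param eps_mm Vector of searching areas to evaluate, millimeters
#'   (default 50, 100, 150, 200 — i.e. 5, 10, 15, 20 cm).
#' @param std Passed to [region_summary()].
#' @return Tibble of class `fusion_sweep`: `eps_mm`, `region`, `ae_mm`,
#'   `std_mm`, `rmse_mm`, `n`.
#' @export
sweep_eps <- function(stream, truth, config = fusion_config(),
                      eps_mm = c(50, 100, 150, 200), std = "population") {
  if (length(eps_mm) < 1 || any(eps_mm <= 0)) {
    stop("invalid config: eps_mm values must be positive", call. = FALSE)
  }
  out <- purrr::map_dfr(eps_mm, function(e) {
    merged <- fuse_sequence(stream, config_with(config, eps_mm = e))
    region_summary(joint_errors(merged, truth), std = std) |>
      dplyr::mutate(eps_mm = e, .before = 1)
  })
  class(out) <- c("fusion_sweep", class(out))
  attr(out, "axis") <- "eps_mm"
  out
}

#' Sweep the number of sensors used for merging
#'
#' For each subset size `k`, fuses every size-`k` combination of the
#' available sensors and averages the region error statistics over the
#' combinations. `k = 1` bypasses merging and scores each sensor's raw
#' stream directly.
#'
#' @inheritParams sweep_eps
#' @param k Subset sizes to evaluate (default 1 up to the number of
#'   sensors).
#' @return Tibble of class `fusion_sweep`: `n_sensors`, `n_combinations`,
#'   `region`, `ae_mm`, `std_mm`, `rmse_mm`.
#' @export
sweep_sensors <- function(stream, truth, config = fusion_config(), k = NULL,
                          std = "population") {
  sensors <- sort(unique(stream$sensor_id))
  if (is.null(k)) k <- seq_along(sensors)
  if (any(k < 1) || any(k > length(sensors))) {
    stop("invalid config: k must be between 1 and the number of sensors",
         call. = FALSE)
  }
  out <- purrr::map_dfr(k, function(kk) {
    combos <- utils::combn(sensors, kk, simplify = FALSE)
    summaries <- purrr::map(combos, function(subset) {
      sub <- stream[stream$sensor_id %in% subset, ]
      track <- if (kk == 1) {
        sub[sub$confidence != "none", ]
      } else {
        fuse_sequence(sub, config)
      }
      region_summary(joint_errors(track, truth), std = std)
    })
    dplyr::bind_rows(summaries) |>
      dplyr::group_by(.data$region) |>
      dplyr::summarise(ae_mm = mean(.data$ae_mm),
                       std_mm = mean(.data$std_mm),
                       rmse_mm = mean(.data$rmse_mm), .groups = "drop") |>
      dplyr::mutate(n_sensors = kk, n_combinations = length(combos),
                    .before = 1)
  })
  class(out) <- c("fusion_sweep", class(out))
  attr(out, "axis") <- "n_sensors"
  out
}

#' Compare fusion pipeline variants on identical inputs
#'
#' @inheritParams sweep_eps
#' @param variants Character vector of variants (subset of A1, A2, A3, A4,
#'   A5).
#' @return Tibble of class `fusion_sweep`: `variant`, `region`, `ae_mm`,
#'   `std_mm`, `rmse_mm`, `n`.
#' @export
compare_variants <- function(stream, truth, config = fusion_config(),
                             variants = c("A1", "A3", "A4", "A5"),
                             std = "population") {
  stopifnot(length(variants) >= 1,
            all(variants %in% c("A1", "A2", "A3", "A4", "A5")))
  out <- purrr::map_dfr(variants, function(v) {
    merged <- fuse_sequence(stream, config_with(config, variant = v))
    region_summary(joint_errors(merged, truth), std = std) |>
      dplyr::mutate(variant = v, .before = 1)
  })
  class(out) <- c("fusion_sweep", class(out))
  attr(out, "axis") <- "variant"
  out
}
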