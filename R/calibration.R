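#' RANSAC estimation of a sphere center of known radius
#'
#' Finds the center of a sphere of known radius from a segmented 3D point
#' cloud, robust to outliers. Hypotheses are generated by fitting a general
#' sphere through 4 randomly sampled points; a hypothesis is rejected when its
#' fitted radius differs from the known radius by more than `radius_tol_mm`.
#' The hypothesis with the most inliers (points whose distance to the center
#' is within `inlier_tol_mm` of the radius) is refined by fixed-radius
#' least squares (Gauss-Newton) on its inlier set.
#'
#' @param points n x 3 matrix (or data frame) of points, mm; n >= 4.
#' @param radius Known sphere radius, mm.
#' @param iterations Number of RANSAC hypotheses to sample.
#' @param inlier_tol_mm Surface-distance tolerance defining an inlier.
#' @param radius_tol_mm Maximum |fitted radius - radius| for a hypothesis.
#' @param seed Integer seed; results are fully reproducible given it.
#' @return A list of class `sphere_fit` with `center` (length-3, mm),
#'   `inlier_indices`, `iterations_used`, `radius` and `rms_surface_mm`.
#' @examples
#' sph <- r_unit_sphere(50)
#' fit <- ransac_sphere_center(240 * sph, radius = 240, seed = 1)
#' fit$center
#' @export
ransac_sphere_center <- function(points, radius, iterations = 200,
                                 inlier_tol_mm = 10, radius_tol_mm = 20,
                                 seed = 1) {
  points <- as.matrix(points)
  if (nrow(points) < 4) {
    stop("insufficient data: sphere fitting needs at least 4 points",
         call. = FALSE)
  }
  stopifnot(ncol(points) == 3, radius > 0)
  withr::with_seed(seed, {
    best_center <- NULL
    best_inliers <- integer(0)
    for (it in seq_len(iterations)) {
      idx <- sample.int(nrow(points), 4)
      c0 <- solve_sphere_through_4(points[idx, ])
      if (is.null(c0)) next
      if (abs(c0$radius - radius) > radius_tol_mm) next
      d <- sqrt(rowSums(sweep(points, 2, c0$center)^2))
      inl <- which(abs(d - radius) <= inlier_tol_mm)
      if (length(inl) > length(best_inliers)) {
        best_inliers <- inl
        best_center <- c0$center
      }
    }
  })
  if (length(best_inliers) < 4) {
    stop("sphere fit failure: no hypothesis with >= 4 inliers", call. = FALSE)
  }
  center <- refine_sphere_center(points[best_inliers, , drop = FALSE],
                                 radius, best_center)
  d <- sqrt(rowSums(sweep(points, 2, center)^2))
  inl <- which(abs(d - radius) <= inlier_tol_mm)
  structure(list(
    center = center,
    inlier_indices = inl,
    iterations_used = iterations,
    radius = radius,
    rms_surface_mm = sqrt(mean((d[inl] - radius)^2))
  ), class = "sphere_fit")
}

# exact sphere through 4 points; NULL when (near-)coplanar
solve_sphere_through_4 <- function(p) {
  A <- 2 * (p[2:4, ] - matrix(p[1, ], 3, 3, byrow = TRUE))
  b <- rowSums(p[2:4, ]^2) - sum(p[1, ]^2)
  c0 <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(c0) || abs(det(A)) < 1e-6) return(NULL)
  list(center = as.numeric(c0), radius = sqrt(sum((p[1, ] - c0)^2)))
}

# fixed-radius nonlinear least squares on the center
refine_sphere_center <- function(p, radius, center, iter = 15) {
  for (i in seq_len(iter)) {
    diff <- sweep(p, 2, center)
    d <- sqrt(rowSums(diff^2))
    d[d < 1e-12] <- 1e-12
    r <- d - radius                      # residuals
    J <- -diff / d                       # d r_i / d center
    step <- tryCatch(solve(crossprod(J), -crossprod(J, r)),
                     error = function(e) NULL)
    if (is.null(step)) break
    center <- center + as.numeric(step)
    if (max(abs(step)) < 1e-12) break
  }
  center
}

#' Sample points uniformly on the unit sphere
#'
#' Convenience generator used by examples and tests.
#' @param n Number of points.
#' @return n x 3 matrix of unit vectors.
#' @export
r_unit_sphere <- function(n) {
  m <- matrix(stats::rnorm(3 * n), n, 3)
  m / sqrt(rowSums(m^2))
}

#' Build aligned calibration trajectories from per-sensor centroid streams
#'
#' Each sensor observes the 3D centroid of a calibration sphere over a set of
#' synchronized frames. Frames in which one or more sensors miss the object
#' are filtered out; the surviving frames form index-aligned correspondence
#' trajectories between each target sensor and the master sensor.
#'
#' @param centroids Tibble with columns `frame_index`, `sensor_id`, `x_mm`,
#'   `y_mm`, `z_mm`; missing detections are simply absent rows (or NA
#'   positions).
#' @param master_id The sensor whose coordinate system is the registration
#'   target.
#' @return Named list (one per non-master sensor) of
#'   `calibration_trajectory` objects with elements `points_master`,
#'   `points_target` (n x 3 matrices) and `n`.
#' @export
build_trajectories <- function(centroids, master_id) {
  centroids <- tibble::as_tibble(centroids)
  stopifnot(all(c("frame_index", "sensor_id", "x_mm", "y_mm", "z_mm") %in%
                  names(centroids)))
  if (!master_id %in% centroids$sensor_id) {
    stop("master sensor '", master_id, "' not present in centroid streams",
         call. = FALSE)
  }
  pos_ok <- matrixStats_all_finite(
    as.matrix(centroids[, c("x_mm", "y_mm", "z_mm")]))
  centroids <- centroids[pos_ok, ]
  sensors <- unique(centroids$sensor_id)
  common <- Reduce(intersect, split(centroids$frame_index, centroids$sensor_id))
  common <- sort(common)
  if (length(common) < 3) {
    stop("insufficient correspondences: only ", length(common),
         " frames seen by every sensor (>= 3 required)", call. = FALSE)
  }
  get_mat <- function(sid) {
    sub <- centroids[centroids$sensor_id == sid, ]
    sub <- sub[match(common, sub$frame_index), ]
    as.matrix(sub[, c("x_mm", "y_mm", "z_mm")])
  }
  master <- get_mat(master_id)
  out <- lapply(setdiff(sensors, master_id), function(sid) {
    structure(list(points_master = master, points_target = get_mat(sid),
                   n = length(common), sensor_id = sid),
              class = "calibration_trajectory")
  })
  names(out) <- setdiff(sensors, master_id)
  out
}

#' Least-squares rigid registration of corresponding point sets
#'
#' Estimates the rotation `R` and translation `T` minimizing
#' `sum_i || m_i - (R p_i + T) ||^2` over corresponding points `p_i` (target
#' sensor) and `m_i` (master sensor): both sets are centered on their
#' centroids, the 3x3 cross-covariance is decomposed by SVD, and the rotation
#' is recovered with a determinant sign correction that excludes reflections;
#' `T` maps the rotated target centroid onto the master centroid.
#'
#' @param traj A `calibration_trajectory`, or an n x 3 matrix of target points
#'   when `master` is given.
#' @param master Optional n x 3 matrix of master points (when `traj` is a
#'   matrix).
#' @return A list of class `rigid_fit`: `transform` (a [rigid_transform()]
#'   mapping target coordinates into master coordinates), and diagnostics
#'   `covariance` (3x3 cross-covariance), `singular_values`,
#'   `rms_residual_mm`, `reflection_corrected` and `n`.
#' @examples
#' m <- matrix(rnorm(30, sd = 500), 10, 3)
#' tr <- rigid_transform(rotation_z(0.8), c(100, -50, 20))
#' p <- rt_apply(rt_inverse(tr), m)
#' fit <- estimate_rigid_transform(p, m)
#' fit$rms_residual_mm
#' @export
estimate_rigid_transform <- function(traj, master = NULL) {
  if (inherits(traj, "calibration_trajectory")) {
    target <- traj$points_target
    master <- traj$points_master
  } else {
    target <- as.matrix(traj)
    master <- as.matrix(master)
  }
  if (!all(dim(target) == dim(master))) {
    stop("target and master trajectories differ in length", call. = FALSE)
  }
  n <- nrow(target)
  if (n < 3) stop("at least 3 correspondences are required", call. = FALSE)
  if (any(!is.finite(target)) || any(!is.finite(master))) {
    stop("non-finite points in trajectory", call. = FALSE)
  }
  cm <- colMeans(master)
  cp <- colMeans(target)
  Mc <- sweep(master, 2, cm)
  Pc <- sweep(target, 2, cp)
  Cov <- crossprod(Mc, Pc)              # sum (m_i - cm)(p_i - cp)^T
  sv <- svd(Cov)
  # rank check: collinear target points leave the rotation underdetermined
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-300)) {
    stop("degenerate (collinear) trajectory geometry: rotation is not ",
         "identifiable", call. = FALSE)
  }
  d <- sign(det(sv$u %*% t(sv$v)))
  reflection <- d < 0
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  T <- cm - as.numeric(R %*% cp)
  fitted <- sweep(target %*% t(R), 2, T, "+")
  rms <- sqrt(mean(rowSums((master - fitted)^2)))
  structure(list(
    transform = rigid_transform(R, T, check = FALSE),
    covariance = Cov,
    singular_values = sv$d,
    rms_residual_mm = rms,
    reflection_corrected = reflection,
    n = n
  ), class = "rigid_fit")
}

#' @export
print.rigid_fit <- function(x, ...) {
  cat("<rigid_fit> n =", x$n, " rms residual =",
      format(x$rms_residual_mm, digits = 4), "mm\n")
  print(x$transform)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a rigid registration fit
#'
#' `tidy()` returns one row per estimated parameter (the three Euler-style
#' rotation angles about x, y, z and the three translation components);
#' `glance()` returns a one-row model summary.
#'
#' @param x A `rigid_fit` from [estimate_rigid_transform()].
#' @param ... Unused.
#' @export
tidy.rigid_fit <- function(x, ...) {
  R <- x$transform$rotation
  angles <- c(
    atan2(R[3, 2], R[3, 3]),
    -asin(max(-1, min(1, R[3, 1]))),
    atan2(R[2, 1], R[1, 1])
  )
  tibble::tibble(
    term = c("theta_x_rad", "theta_y_rad", "theta_z_rad",
             "t_x_mm", "t_y_mm", "t_z_mm"),
    estimate = c(angles, x$transform$translation)
  )
}

#' @rdname tidy.rigid_fit
#' @export
glance.rigid_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    rms_residual_mm = x$rms_residual_mm,
    reflection_corrected = x$reflection_corrected,
    sv_1 = x$singular_values[1],
    sv_2 = x$singular_values[2],
    sv_3 = x$singular_values[3]
  )
}

#' Calibrate all sensors to a master sensor from sphere-centroid streams
#'
#' Convenience pipeline: [build_trajectories()] then
#' [estimate_rigid_transform()] per sensor. The master sensor is included
#' with an identity transform.
#'
#' @inheritParams build_trajectories
#' @return Tibble with columns `sensor_id`, `transform` (list column of
#'   [rigid_transform()]), `n`, `rms_residual_mm`, `reflection_corrected`.
#' @export
calibrate_sensors <- function(centroids, master_id) {
  trajs <- build_trajectories(centroids, master_id)
  fits <- purrr::map(trajs, estimate_rigid_transform)
  tibble::tibble(
    sensor_id = c(master_id, names(fits)),
    transform = c(list(rt_identity()), unname(purrr::map(fits, "transform"))),
    n = c(NA_integer_, unname(purrr::map_int(fits, "n"))),
    rms_residual_mm = c(0, unname(purrr::map_dbl(fits, "rms_residual_mm"))),
    reflection_corrected = c(FALSE, unname(purrr::map_lgl(
      fits, "reflection_corrected")))
  )
}

#' Global coordinate frame from a four-marker plate
#'
#' Given the 3D centroids of four fiducial markers (indexed 0-3) measured in
#' the master sensor's coordinate system, constructs the user-defined global
#' frame: the x axis runs from marker 1 to marker 2, the provisional y axis
#' from marker 1 to marker 0, the z axis is their (re-normalized) cross
#' product with sign chosen to point floor-to-ceiling (positive dot product
#' with `up_hint`), and y is re-orthogonalized as `z x x` (the measured marker
#' vectors need not be perpendicular). The origin is marker 1's centroid.
#'
#' @param centroids 4 x 3 matrix of marker centroids in rows 0,1,2,3 order,
#'   or a named list with elements `"0"`..`"3"`, mm.
#' @param up_hint Direction (sensor coordinates) known to point upward; used
#'   only for the sign of the z axis. Default `c(0, -1, 0)`, the camera-up of
#'   a typical depth sensor whose y axis points down.
#' @return A [rigid_transform()] mapping master-sensor coordinates into the
#'   global (marker) frame.
#' @export
marker_frame <- function(centroids, up_hint = c(0, -1, 0)) {
  if (is.list(centroids) && !is.data.frame(centroids)) {
    centroids <- do.call(rbind, centroids[as.character(0:3)])
  }
  centroids <- as.matrix(centroids)
  stopifnot(nrow(centroids) == 4, ncol(centroids) == 3)
  c0 <- centroids[1, ]; c1 <- centroids[2, ]; c2 <- centroids[3, ]
  xv <- c2 - c1
  yv <- c0 - c1
  zraw <- cross3(xv, yv)
  area2 <- sqrt(sum(zraw^2))
  if (area2 < 1e-6 * max(sqrt(sum(xv^2)) * sqrt(sum(yv^2)), 1e-300) ||
      area2 == 0) {
    stop("degenerate marker frame: markers 0, 1, 2 are collinear",
         call. = FALSE)
  }
  xhat <- xv / sqrt(sum(xv^2))
  zhat <- zraw / area2
  if (sum(zhat * up_hint) < 0) zhat <- -zhat
  yhat <- cross3(zhat, xhat)
  R <- rbind(xhat, yhat, zhat)
  dimnames(R) <- NULL
  rigid_transform(R, as.numeric(-R %*% c1))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Elementary rotation about the z axis
#' @param angle Angle in radians.
#' @return 3x3 rotation matrix.
#' @export
rotation_z <- function(angle) rotation_about(c(0, 0, 1), angle)
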