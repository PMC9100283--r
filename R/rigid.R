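#' Rigid transforms (rotation + translation)
#'
#' A rigid transform maps points `p` (row vectors, mm) to `R %*% p + t`. The
#' rotation must be orthonormal with determinant +1 (no reflection).
#'
#' @param rotation 3x3 orthonormal rotation matrix.
#' @param translation Length-3 translation vector, millimeters.
#' @param check Verify the orthonormality/determinant invariants.
#' @return An object of class `rigid_transform`.
#' @examples
#' t1 <- rigid_transform(diag(3), c(10, 0, 0))
#' rt_apply(t1, c(1, 2, 3))
#' @export
rigid_transform <- function(rotation, translation = c(0, 0, 0), check = TRUE) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation)
  stopifnot(length(translation) == 3)
  if (check) {
    if (max(abs(crossprod(rotation) - diag(3))) > 1e-9) {
      stop("rotation is not orthonormal within 1e-9", call. = FALSE)
    }
    if (abs(det(rotation) - 1) > 1e-9) {
      stop("rotation determinant is not +1 within 1e-9 (reflection?)",
           call. = FALSE)
    }
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @export
rt_identity <- function() rigid_transform(diag(3), c(0, 0, 0), check = FALSE)

#' @rdname rigid_transform
#' @param x Object to test.
#' @export
is_rigid_transform <- function(x) inherits(x, "rigid_transform")

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n")
  cat("rotation:\n")
  print(round(x$rotation, 6))
  cat("translation (mm):", round(x$translation, 3), "\n")
  invisible(x)
}

#' Compose, invert and apply rigid transforms
#'
#' `rt_compose(a, b)` returns the transform equivalent to applying `b` first,
#' then `a`: `rt_apply(rt_compose(a, b), p) == rt_apply(a, rt_apply(b, p))`.
#'
#' @param a,b,t `rigid_transform` objects.
#' @param p A length-3 vector or an n x 3 matrix of points (mm).
#' @export
rt_compose <- function(a, b) {
  stopifnot(is_rigid_transform(a), is_rigid_transform(b))
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation,
                  check = FALSE)
}

#' @rdname rt_compose
#' @export
rt_inverse <- function(t) {
  stopifnot(is_rigid_transform(t))
  rigid_transform(t(t$rotation),
                  as.numeric(-t(t$rotation) %*% t$translation),
                  check = FALSE)
}

#' @rdname rt_compose
#' @export
rt_apply <- function(t, p) {
  stopifnot(is_rigid_transform(t))
  if (is.null(dim(p))) {
    return(as.numeric(t$rotation %*% p + t$translation))
  }
  p <- as.matrix(p)
  stopifnot(ncol(p) == 3)
  sweep(p %*% t(t$rotation), 2, t$translation, "+")
}

#' Apply a rigid transform to a skeleton stream
#'
#' Transforms the positions of every observation; confidences and all other
#' columns are unchanged. Rows with missing positions (confidence `none`) are
#' left as-is. `transform` may be a single `rigid_transform` applied to all
#' rows, or a named list of transforms keyed by `sensor_id` (each sensor's
#' observations are mapped by its own transform, e.g. after extrinsic
#' calibration).
#'
#' @param stream Skeleton stream tibble (see [validate_stream()]).
#' @param transform A `rigid_transform` or a named list of them by sensor id.
#' @return The transformed stream tibble.
#' @export
apply_transform <- function(stream, transform) {
  stream <- tibble::as_tibble(stream)
  pos <- as.matrix(stream[, c("x_mm", "y_mm", "z_mm")])
  ok <- matrixStats_all_finite(pos)
  if (is_rigid_transform(transform)) {
    pos[ok, ] <- rt_apply(transform, pos[ok, , drop = FALSE])
  } else {
    stopifnot(is.list(transform))
    missing_ids <- setdiff(unique(stream$sensor_id), names(transform))
    if (length(missing_ids) > 0) {
      stop("no transform for sensor(s): ", paste(missing_ids, collapse = ", "),
           call. = FALSE)
    }
    for (sid in unique(stream$sensor_id)) {
      idx <- ok & stream$sensor_id == sid
      pos[idx, ] <- rt_apply(transform[[sid]], pos[idx, , drop = FALSE])
    }
  }
  stream$x_mm <- pos[, 1]
  stream$y_mm <- pos[, 2]
  stream$z_mm <- pos[, 3]
  stream
}

# small helper: rotation about an axis by angle (radians)
rotation_about <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}
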