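#' Read and write skeleton stream files
#'
#' Streams are stored as CSV (comma separated, UTF-8, mandatory header,
#' `.` decimal separator) or JSON Lines with fields `frame_index`,
#' `timestamp_s` (optional), `sensor_id`, `joint`, `x_mm`, `y_mm`, `z_mm`,
#' `confidence` (literal `medium`/`low`/`none`). Readers validate the schema
#' and reject non-finite positions on rows whose confidence is not `none`,
#' reporting the offending line. `write_skeleton_stream()` followed by
#' `read_skeleton_stream()` reproduces positions to well below 1e-6 mm.
#'
#' @param path File path; the format is inferred from the extension
#'   (`.csv` or `.jsonl`) unless `format` is given.
#' @param format `"csv"` or `"jsonl"`.
#' @return `read_skeleton_stream()` returns a validated stream tibble.
#' @export
read_skeleton_stream <- function(path, format = NULL) {
  format <- stream_format(path, format)
  if (format == "csv") {
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    df <- tibble::as_tibble(jsonlite::stream_in(file(path), verbose = FALSE))
  }
  df <- coerce_stream_types(df, path)
  tryCatch(validate_stream(df), error = function(e) {
    stop("schema error in ", path, ": ", conditionMessage(e), call. = FALSE)
  })
}

#' @rdname read_skeleton_stream
#' @param stream Stream tibble to write.
#' @export
write_skeleton_stream <- function(stream, path, format = NULL) {
  format <- stream_format(path, format)
  stream <- validate_stream(stream)
  if (format == "csv") {
    readr::write_csv(stream, path, progress = FALSE)
  } else {
    con <- file(path, open = "w")
    on.exit(close(con))
    jsonlite::stream_out(as.data.frame(stream), con, verbose = FALSE,
                         digits = NA, na = "null")
  }
  invisible(path)
}

stream_format <- function(path, format) {
  if (!is.null(format)) return(match.arg(format, c("csv", "jsonl")))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("jsonl", "ndjson", "json")) "jsonl" else "csv"
}

coerce_stream_types <- function(df, path) {
  required <- c("frame_index", "sensor_id", "joint", "x_mm", "y_mm", "z_mm",
                "confidence")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("schema error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df$frame_index <- as.integer(df$frame_index)
  df$sensor_id <- as.character(df$sensor_id)
  df$joint <- as.character(df$joint)
  df$confidence <- as.character(df$confidence)
  for (col in c("x_mm", "y_mm", "z_mm")) df[[col]] <- as.numeric(df[[col]])
  bad <- which(!df$confidence %in% confidence_levels())
  if (length(bad) > 0) {
    stop("parse error in ", path, " line ", bad[1] + 1L,
         ": invalid confidence value '", df$confidence[bad[1]], "'",
         call. = FALSE)
  }
  df
}

#' Read and write extrinsic calibration files
#'
#' Calibration files are JSON arrays with one object per sensor:
#' `sensor_id`, `rotation` (9 row-major floats), `translation_mm`
#' (3 floats) and optional `diagnostics`.
#'
#' @param path File path.
#' @return `read_calibration()` returns a named list of
#'   [rigid_transform()] objects keyed by sensor id.
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  out <- lapply(obj, function(entry) {
    rot <- matrix(as.numeric(unlist(entry$rotation)), 3, 3, byrow = TRUE)
    rigid_transform(rot, as.numeric(unlist(entry$translation_mm)))
  })
  names(out) <- vapply(obj, function(e) as.character(e$sensor_id),
                       character(1))
  out
}

#' @rdname read_calibration
#' @param calibration A tibble from [calibrate_sensors()] or a named list of
#'   [rigid_transform()] objects.
#' @export
write_calibration <- function(calibration, path) {
  if (is.data.frame(calibration)) {
    entries <- purrr::pmap(calibration, function(sensor_id, transform, ...) {
      extra <- list(...)
      c(list(sensor_id = sensor_id,
             rotation = as.numeric(t(transform$rotation)),
             translation_mm = transform$translation),
        list(diagnostics = extra))
    })
  } else {
    entries <- purrr::imap(calibration, function(tr, sid) {
      list(sensor_id = sid, rotation = as.numeric(t(tr$rotation)),
           translation_mm = tr$translation)
    })
  }
  jsonlite::write_json(unname(entries), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Parse a searching-area value with an explicit unit suffix
#'
#' Accepts numbers with a `mm` or `cm` suffix (e.g. `"10cm"`, `"100mm"`) or
#' bare numbers (interpreted as millimeters) and returns millimeters.
#'
#' @param x Character or numeric scalar/vector.
#' @return Numeric vector in millimeters.
#' @examples
#' parse_eps("10cm") == parse_eps("100mm")
#' @export
parse_eps <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- trimws(as.character(x))
  m <- regmatches(x, regexec("^([0-9]*\\.?[0-9]+)\\s*(mm|cm)?$", x))
  vapply(seq_along(x), function(i) {
    parts <- m[[i]]
    if (length(parts) == 0 || parts[1] == "") {
      stop("unit-suffix violation: cannot parse searching area '", x[i],
           "' (use e.g. '10cm' or '100mm')", call. = FALSE)
    }
    val <- as.numeric(parts[2])
    if (identical(parts[3], "cm")) val * 10 else val
  }, numeric(1))
}

#' Read a fusion configuration file
#'
#' YAML key-value file with sections `fusion`, `kalman` and `dbscan`, e.g.:
#' ```yaml
#' fusion:
#'   variant: A5
#'   max_predict_frames: 30
#' dbscan:
#'   eps: 10cm
#'   min_neighbors: 1
#' kalman:
#'   q: 0.01
#'   r: 1.0
#' ```
#' The searching area accepts an explicit `cm` or `mm` unit suffix.
#'
#' @param path YAML file path.
#' @return A [fusion_config()].
#' @export
read_fusion_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  fus <- cfg$fusion %||% list()
  dbs <- cfg$dbscan %||% list()
  kal <- cfg$kalman %||% list()
  args <- list(
    variant = fus$variant %||% "A5",
    eps_mm = parse_eps(dbs$eps %||% fus$eps %||% 100),
    min_neighbors = dbs$min_neighbors %||% 1L,
    kalman = kalman_config(q = kal$q %||% 0.01, r = kal$r %||% 1.0),
    max_predict_frames = fus$max_predict_frames %||% 30L
  )
  if (!is.null(fus$use_reference_candidate)) {
    args$use_reference_candidate <- fus$use_reference_candidate
  }
  if (!is.null(fus$use_previous_candidate)) {
    args$use_previous_candidate <- fus$use_previous_candidate
  }
  if (!is.null(fus$arrange)) args$arrange <- fus$arrange
  do.call(fusion_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
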