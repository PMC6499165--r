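# Neutral motor-map table I/O.
#
# Vendor neuronavigation exports (Nexstim, BrainSight) are proprietary and
# undocumented, so the package defines a neutral schema instead:
#   CSV with header  x_mm, y_mm, z_mm, mep_uv
# plus an optional JSON sidecar (<stem>.json) carrying the reference point
# and a session label.  Coordinates are scanner mm: +x right->left of image
# (left->right anatomical), +y posterior->anterior, +z inferior->superior.

MOTOR_MAP_COLUMNS <- c("x_mm", "y_mm", "z_mm", "mep_uv")

#' Construct a motor map dataset
#'
#' A motor map is a set of stimulation events: a 3D position on the scalp in
#' scanner mm and the peak-to-peak MEP amplitude (microvolt) evoked there.
#'
#' @param x,y,z numeric event coordinates in mm.
#' @param value numeric MEP peak-to-peak amplitudes in microvolt (>= 0).
#' @param reference_point optional length-3 numeric, the reference point in mm
#'   used for position reporting; `NULL` if none was imported.
#' @param reference_source one of `"imported"`, `"centroid_default"`,
#'   `"user_set"`.
#' @param session_label optional free-text label for the recording session.
#' @return An object of class `motor_map`: a data.frame with columns
#'   `x`, `y`, `z`, `value` and attributes `reference_point`,
#'   `reference_source`, `session_label`.
#' @export
motor_map <- function(x, y, z, value, reference_point = NULL,
                      reference_source = "imported", session_label = NULL) {
  n <- length(x)
  if (n < 1L) stop_mm("empty_file_error", "a motor map needs at least one event")
  if (length(y) != n || length(z) != n || length(value) != n) {
    stop_mm("schema_error", "x, y, z and value must have equal length")
  }
  x <- as.numeric(x); y <- as.numeric(y); z <- as.numeric(z)
  value <- as.numeric(value)
  assert_finite(cbind(x, y, z), "event coordinates")
  if (any(!is.finite(value)) || any(value < 0)) {
    stop_mm("value_error", "MEP values must be finite and >= 0")
  }
  if (!is.null(reference_point)) {
    reference_point <- as.numeric(reference_point)
    if (length(reference_point) != 3L) {
      stop_mm("value_error", "reference_point must have 3 coordinates")
    }
    assert_finite(reference_point, "reference_point")
    reference_source <- match.arg(reference_source,
                                  c("imported", "centroid_default", "user_set"))
  }
  structure(
    data.frame(x = x, y = y, z = z, value = value),
    reference_point = reference_point,
    reference_source = if (is.null(reference_point)) NULL else reference_source,
    session_label = session_label,
    class = c("motor_map", "data.frame")
  )
}

#' @export
print.motor_map <- function(x, ...) {
  cat(sprintf("<motor_map> %d stimulation events\n", nrow(x)))
  if (!is.null(attr(x, "session_label"))) {
    cat("  session:", attr(x, "session_label"), "\n")
  }
  rp <- attr(x, "reference_point")
  if (!is.null(rp)) {
    cat(sprintf("  reference point (%s): %.2f, %.2f, %.2f mm\n",
                attr(x, "reference_source"), rp[1], rp[2], rp[3]))
  }
  cat(sprintf("  MEP range: %.1f - %.1f uV\n", min(x$value), max(x$value)))
  invisible(x)
}

#' @export
summary.motor_map <- function(object, ...) {
  cat(sprintf("Motor map with %d events\n", nrow(object)))
  print(summary(object$value))
  invisible(object)
}

sidecar_path <- function(path) sub("\\.csv$", ".json", path)

#' Read a motor map from the neutral CSV schema
#'
#' Expects a header `x_mm,y_mm,z_mm,mep_uv` (extra columns such as
#' `cluster_id` are kept as plain columns). If a sidecar JSON `<stem>.json`
#' exists next to the file, the reference point and session label are read
#' from it.
#'
#' @param path path to a CSV file.
#' @return A [motor_map].
#' @export
read_motor_map <- function(path) {
  if (!file.exists(path)) stop_mm("io_error", sprintf("file not found: %s", path))
  df <- tryCatch(
    utils::read.csv(path, check.names = FALSE, colClasses = NA),
    error = function(e) stop_mm("io_error", conditionMessage(e))
  )
  if (nrow(df) == 0L) stop_mm("empty_file_error", sprintf("no data rows in %s", path))
  missing <- setdiff(MOTOR_MAP_COLUMNS, names(df))
  if (length(missing)) {
    stop_mm("schema_error",
            sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
  }
  for (col in MOTOR_MAP_COLUMNS) {
    if (!is.numeric(df[[col]])) {
      suppressWarnings(conv <- as.numeric(as.character(df[[col]])))
      if (any(is.na(conv))) {
        stop_mm("value_error", sprintf("non-numeric entries in column %s", col))
      }
      df[[col]] <- conv
    }
  }
  ref <- NULL; ref_src <- "imported"; label <- NULL
  sc <- sidecar_path(path)
  if (sc != path && file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (!is.null(meta$reference_point)) ref <- as.numeric(meta$reference_point)
    if (!is.null(meta$reference_source)) ref_src <- meta$reference_source
    if (!is.null(meta$session_label)) label <- meta$session_label
  }
  m <- motor_map(df$x_mm, df$y_mm, df$z_mm, df$mep_uv,
                 reference_point = ref, reference_source = ref_src,
                 session_label = label)
  extra <- setdiff(names(df), MOTOR_MAP_COLUMNS)
  for (col in extra) m[[col]] <- df[[col]]
  m
}

#' Write a motor map in the neutral CSV schema
#'
#' Writes `x_mm,y_mm,z_mm,mep_uv` (plus any extra columns, e.g. `cluster_id`)
#' and, when the map carries a reference point or session label, a JSON
#' sidecar `<stem>.json`.
#'
#' @param map a [motor_map].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_motor_map <- function(map, path) {
  stopifnot(inherits(map, "motor_map"))
  df <- as.data.frame(map)
  names(df)[match(c("x", "y", "z", "value"), names(df))] <- MOTOR_MAP_COLUMNS
  ok <- tryCatch({ utils::write.csv(df, path, row.names = FALSE); TRUE },
                 error = function(e) stop_mm("io_error", conditionMessage(e)))
  rp <- attr(map, "reference_point")
  label <- attr(map, "session_label")
  if (!is.null(rp) || !is.null(label)) {
    meta <- list()
    if (!is.null(rp)) {
      meta$reference_point <- rp
      meta$reference_source <- attr(map, "reference_source")
    }
    if (!is.null(label)) meta$session_label <- label
    jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Write a measurement report
#'
#' Renders a `map_measurements` object (see [measure_map()]) as JSON
#' (units embedded per field) and/or CSV (units embedded in the header).
#'
#' @param report a `map_measurements` object.
#' @param path output path; extension decides the format (`.json` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "map_measurements"))
  flat <- list(
    cog_mm = unname(report$cog),
    peak_position_mm = unname(report$peak$position),
    peak_value_uv = report$peak$value,
    surface_area_mm2 = report$surface_area,
    volume_integral_uv_mm2 = report$volume_integral,
    reference_point_mm = unname(report$reference_point),
    cog_to_reference_mm = unname(unlist(report$cog_to_reference)),
    peak_to_reference_mm = unname(unlist(report$peak_to_reference))
  )
  if (grepl("\\.json$", path)) {
    tryCatch(jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA),
             error = function(e) stop_mm("io_error", conditionMessage(e)))
  } else if (grepl("\\.csv$", path)) {
    vals <- unlist(flat)
    df <- data.frame(field = names(vals), value = as.numeric(vals))
    tryCatch(utils::write.csv(df, path, row.names = FALSE),
             error = function(e) stop_mm("io_error", conditionMessage(e)))
  } else {
    stop_mm("value_error", "report path must end in .json or .csv")
  }
  invisible(path)
}

#' Read a JSON measurement report written by [write_report()]
#'
#' @param path path to the JSON report.
#' @return A named list of report fields.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop_mm("io_error", sprintf("file not found: %s", path))
  jsonlite::read_json(path, simplifyVector = TRUE)
}
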