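#' Measurement tools
#'
#' All geometric tools work in image coordinates: origin at the top-left
#' pixel center, x to the right, y downward, sub-pixel positions allowed.
#' This is the canvas/screen convention; note that DICOM indexes pixels as
#' (row, column), i.e. (y, x) in this frame. Zoom and pan in a viewer never
#' change these coordinates, so stored raw values are viewer-independent.
#'
#' Raw values are in pixels (length), square pixels (area), degrees (angle),
#' counts, or intensity (probe). A [calibration()] converts length and area
#' to mm and mm^2; angles, counts and probes are scale-free.
#'
#' @name measurement-tools
NULL

as_point <- function(p, what = "point") {
  if (is.list(p) && !is.null(p$x)) p <- c(p$x, p$y)
  bs_check(is.numeric(p) && length(p) == 2L && all(is.finite(p)),
           "validation", sprintf("%s must be two finite coordinates (x, y)", what))
  as.numeric(p)
}

as_points <- function(pts) {
  if (is.matrix(pts)) {
    bs_check(ncol(pts) == 2L, "validation", "point matrix must have columns x, y")
    return(unname(pts))
  }
  if (is.data.frame(pts)) return(cbind(pts$x, pts$y))
  if (length(pts) == 0L) return(matrix(numeric(0), ncol = 2))
  do.call(rbind, lapply(pts, as_point))
}

new_measurement <- function(kind, points, raw_value, units,
                            calibrated_value = NULL, calibrated_units = NULL,
                            flags = character()) {
  structure(list(kind = kind, points = points, raw_value = raw_value,
                 units = units, calibrated_value = calibrated_value,
                 calibrated_units = calibrated_units, flags = flags),
            class = "bs_measurement")
}

#' @export
print.bs_measurement <- function(x, ...) {
  cat("<measurement:", x$kind, "> ",
      format(x$raw_value, digits = 6), " ", x$units, sep = "")
  if (!is.null(x$calibrated_value))
    cat(" = ", format(x$calibrated_value, digits = 6), " ", x$calibrated_units, sep = "")
  if (length(x$flags)) cat("  [", paste(x$flags, collapse = ", "), "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Image scale calibration
#'
#' A calibration maps pixels to millimetres. Sources: `dicom_metadata`
#' (PixelSpacing read at ingestion), `manual_scale` (factor typed in), or
#' `known_object` (derived from an object of known physical length, e.g. a
#' 25 or 30 mm ball marker in orthopedic radiographs). Anisotropic DICOM
#' spacing is supported by giving distinct row/column spacings; lengths then
#' combine the per-axis terms in quadrature and areas use row x column
#' spacing per px^2.
#'
#' @param scale_mm_per_px isotropic scale in mm per pixel.
#' @param source provenance of the scale.
#' @param row_mm_per_px,col_mm_per_px optional anisotropic spacings
#'   (mm per pixel along image rows / columns); default to the isotropic scale.
#' @return a `bs_calibration`.
#' @export
#' @examples
#' calibration(0.1, "manual_scale")
calibration <- function(scale_mm_per_px,
                        source = c("manual_scale", "dicom_metadata", "known_object"),
                        row_mm_per_px = scale_mm_per_px,
                        col_mm_per_px = scale_mm_per_px) {
  source <- match.arg(source)
  bs_check(is_num1(scale_mm_per_px) && scale_mm_per_px > 0,
           "validation", "scale must be a finite positive number")
  bs_check(is_num1(row_mm_per_px) && row_mm_per_px > 0 &&
             is_num1(col_mm_per_px) && col_mm_per_px > 0,
           "validation", "row/col spacing must be finite positive numbers")
  structure(list(scale_mm_per_px = scale_mm_per_px,
                 row_mm_per_px = row_mm_per_px, col_mm_per_px = col_mm_per_px,
                 anisotropic = !isTRUE(all.equal(row_mm_per_px, col_mm_per_px)),
                 source = source),
            class = "bs_calibration")
}

#' @export
print.bs_calibration <- function(x, ...) {
  cat("<calibration> ", format(x$scale_mm_per_px, digits = 6), " mm/px (",
      x$source, if (x$anisotropic) ", anisotropic", ")\n", sep = "")
  invisible(x)
}

#' Calibrate from an object of known length
#'
#' @param measured_px measured size of the object in pixels (> 0).
#' @param known_length_mm true physical length in mm (> 0).
#' @return a `bs_calibration` with source `known_object`.
#' @export
#' @examples
#' calibrate_known_object(250, 25)  # 25 mm ball marker spanning 250 px -> 0.1 mm/px
calibrate_known_object <- function(measured_px, known_length_mm) {
  bs_check(is_num1(measured_px) && measured_px > 0,
           "validation", "measured_px must be positive")
  bs_check(is_num1(known_length_mm) && known_length_mm > 0,
           "validation", "known_length_mm must be positive")
  calibration(known_length_mm / measured_px, "known_object")
}

#' Distance between two points
#'
#' @param p1,p2 points as `c(x, y)` in image coordinates.
#' @param cal optional [calibration()]; when present the calibrated value in
#'   mm is attached (anisotropic spacing combined in quadrature per axis).
#' @return a `bs_measurement` of kind `length`.
#' @export
measure_length <- function(p1, p2, cal = NULL) {
  p1 <- as_point(p1, "p1"); p2 <- as_point(p2, "p2")
  d <- p2 - p1
  raw <- sqrt(sum(d^2))
  m <- new_measurement("length", rbind(p1, p2), raw, "px")
  if (!is.null(cal)) {
    bs_check(inherits(cal, "bs_calibration"), "validation", "cal must be a bs_calibration")
    mm <- sqrt((d[1] * cal$col_mm_per_px)^2 + (d[2] * cal$row_mm_per_px)^2)
    m$calibrated_value <- mm
    m$calibrated_units <- "mm"
  }
  m
}

#' Interior angle at a vertex
#'
#' The angle between rays vertex->p1 and vertex->p3, in degrees within
#' \[0, 180\]. Scale-invariant: no calibration ever applies.
#'
#' @param p1,vertex,p3 points; `p1` and `p3` must differ from `vertex`.
#' @return a `bs_measurement` of kind `angle`.
#' @export
measure_angle <- function(p1, vertex, p3) {
  p1 <- as_point(p1, "p1"); v <- as_point(vertex, "vertex"); p3 <- as_point(p3, "p3")
  u <- p1 - v; w <- p3 - v
  bs_check(sum(u^2) > 0 && sum(w^2) > 0, "validation",
           "angle rays are degenerate: endpoint coincides with the vertex")
  cosang <- sum(u * w) / sqrt(sum(u^2) * sum(w^2))
  ang <- acos(min(1, max(-1, cosang))) * 180 / pi
  new_measurement("angle", rbind(p1, v, p3), ang, "deg")
}

#' Freehand polygon area (shoelace)
#'
#' Area of the implicitly closed polygon through the given vertices, by the
#' absolute value of the signed shoelace sum divided by two. For a
#' self-intersecting outline, regions of opposite winding cancel under this
#' convention; that is the documented behaviour (intersections are not
#' detected).
#'
#' @param polygon at least 3 points (list of `c(x, y)`, 2-column matrix, or
#'   data frame with `x`, `y`).
#' @param cal optional [calibration()]; area converts with the square of the
#'   scale (row x column spacing when anisotropic).
#' @return a `bs_measurement` of kind `area`.
#' @export
#' @examples
#' measure_area(rbind(c(0, 0), c(4, 0), c(0, 3)))  # 6 px^2
measure_area <- function(polygon, cal = NULL) {
  pts <- as_points(polygon)
  bs_check(nrow(pts) >= 3L, "validation", "a polygon needs at least 3 points")
  x <- pts[, 1]; y <- pts[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  raw <- abs(sum(x * yn - xn * y)) / 2
  m <- new_measurement("area", pts, raw, "px^2")
  if (!is.null(cal)) {
    bs_check(inherits(cal, "bs_calibration"), "validation", "cal must be a bs_calibration")
    m$calibrated_value <- raw * cal$row_mm_per_px * cal$col_mm_per_px
    m$calibrated_units <- "mm^2"
  }
  m
}

#' Count placed markers
#'
#' @param points marker positions (possibly empty).
#' @param roi optional rectangular region of interest
#'   `c(xmin, ymin, xmax, ymax)`; only markers inside it (boundary inclusive)
#'   are counted.
#' @return a `bs_measurement` of kind `count`.
#' @export
count_markers <- function(points, roi = NULL) {
  pts <- as_points(points)
  n <- nrow(pts)
  if (!is.null(roi) && n > 0L) {
    bs_check(is.numeric(roi) && length(roi) == 4L, "validation",
             "roi must be c(xmin, ymin, xmax, ymax)")
    inside <- pts[, 1] >= roi[1] & pts[, 1] <= roi[3] &
              pts[, 2] >= roi[2] & pts[, 2] <= roi[4]
    n <- sum(inside)
    pts <- pts[inside, , drop = FALSE]
  }
  new_measurement("count", pts, as.integer(n), "markers")
}

#' Probe the pixel value at a point
#'
#' Reports the value of the nearest integer pixel: a single grayscale
#' intensity, or an RGB triple. For DICOM frames the stored value is mapped
#' through the rescale slope/intercept when present (so CT probes report
#' Hounsfield-style units rather than stored integers).
#'
#' @param frame a `bs_frame` as returned by [load_frame()] or [decode_frame()].
#' @param p probe point in image coordinates; must lie within the image.
#' @return a `bs_measurement` of kind `probe`; `raw_value` has length 1
#'   (gray) or 3 (RGB).
#' @export
probe_pixel <- function(frame, p) {
  bs_check(inherits(frame, "bs_frame"), "validation", "frame must be a bs_frame")
  p <- as_point(p)
  j <- as.integer(round(p[1])) + 1L  # column
  i <- as.integer(round(p[2])) + 1L  # row
  h <- dim(frame$pixels)[1]; w <- dim(frame$pixels)[2]
  bs_check(i >= 1L && i <= h && j >= 1L && j <= w,
           "validation", "probe point is outside the image")
  val <- if (length(dim(frame$pixels)) == 3L) frame$pixels[i, j, ] else frame$pixels[i, j]
  val <- as.numeric(val)
  if (!is.null(frame$rescale_slope)) {
    val <- val * frame$rescale_slope + (frame$rescale_intercept %||% 0)
  }
  new_measurement("probe", rbind(p), val, frame$value_units %||% "intensity")
}

#' Apply a calibration to an existing measurement
#'
#' Lengths convert as px x scale, areas as px^2 x scale^2. Angles, counts and
#' probes are scale-free: they are returned unchanged with a warning.
#'
#' @param m a `bs_measurement`.
#' @param cal a [calibration()].
#' @return the measurement with `calibrated_value`/`calibrated_units` set.
#' @export
convert_measurement <- function(m, cal) {
  bs_check(inherits(m, "bs_measurement"), "validation", "m must be a bs_measurement")
  bs_check(inherits(cal, "bs_calibration"), "validation", "cal must be a bs_calibration")
  if (m$kind == "length") {
    d <- m$points[2, ] - m$points[1, ]
    m$calibrated_value <- sqrt((d[1] * cal$col_mm_per_px)^2 + (d[2] * cal$row_mm_per_px)^2)
    m$calibrated_units <- "mm"
  } else if (m$kind == "area") {
    m$calibrated_value <- m$raw_value * cal$row_mm_per_px * cal$col_mm_per_px
    m$calibrated_units <- "mm^2"
  } else {
    warning(sprintf("'%s' measurements are scale-free; calibration not applied", m$kind))
  }
  m
}

#' Serialize / restore measurements
#'
#' Measurements embed in response records as a compact JSON array; this is
#' the schema flattened into the CSV export.
#'
#' @param ms list of `bs_measurement` objects.
#' @return `measurements_to_json()`: a JSON string; `measurements_from_json()`:
#'   a list of `bs_measurement`.
#' @export
measurements_to_json <- function(ms) {
  if (inherits(ms, "bs_measurement")) ms <- list(ms)
  items <- lapply(ms, function(m) {
    list(kind = m$kind,
         points = lapply(seq_len(nrow(m$points)),
                         function(i) c(x = m$points[i, 1], y = m$points[i, 2])),
         raw_value = m$raw_value, units = m$units,
         calibrated_value = m$calibrated_value,
         calibrated_units = m$calibrated_units)
  })
  as.character(jsonlite::toJSON(items, auto_unbox = TRUE, null = "null", digits = NA))
}

#' @rdname measurements_to_json
#' @param json JSON produced by `measurements_to_json()`.
#' @export
measurements_from_json <- function(json) {
  items <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  lapply(items, function(it) {
    pts <- do.call(rbind, lapply(it$points, function(p) c(p$x, p$y)))
    new_measurement(it$kind, pts, unlist(it$raw_value), it$units,
                    it$calibrated_value, it$calibrated_units)
  })
}
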