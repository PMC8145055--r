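#' Build the landmark-based femoral coordinate frame
#'
#' The traditional manual measurement workflow establishes a femoral
#' coordinate system from picked landmarks: the medullary-cavity centerline
#' (line L, through two picked points) is the z-axis, positive toward the
#' greater trochanter; the x-axis runs from its foot point through the
#' farthest lesser-trochanter point A, perpendicular to z; the y-axis is
#' z cross x; the origin O is the foot of the perpendicular from A to L.
#'
#' @param axis_point_1,axis_point_2 two distinct points on the medullary
#'   centerline (mm).
#' @param lesser_trochanter point A, off the centerline.
#' @param toward_greater_trochanter any point indicating the +z side.
#' @param side optional `"left"`/`"right"` tag (metadata only; the
#'   cross-product rule fixes the handedness on both sides).
#' @return object of class `"femoral_frame"` with `origin`, `x_axis`,
#'   `y_axis`, `z_axis`, `side`.
#' @export
build_femoral_frame <- function(axis_point_1, axis_point_2, lesser_trochanter,
                                toward_greater_trochanter, side = NULL) {
  p1 <- check_point3(axis_point_1, "axis_point_1")
  p2 <- check_point3(axis_point_2, "axis_point_2")
  A <- check_point3(lesser_trochanter, "lesser_trochanter")
  gt <- check_point3(toward_greater_trochanter, "toward_greater_trochanter")
  d <- p2 - p1
  if (sqrt(sum(d^2)) < 1e-9)
    stop("axis points must be distinct", call. = FALSE)
  z <- d / sqrt(sum(d^2))
  # foot of the perpendicular from A to line L
  origin <- p1 + sum((A - p1) * z) * z
  xv <- A - origin
  if (sqrt(sum(xv^2)) < 1e-6)
    stop("degenerate frame: lesser trochanter point lies on the axis line",
         call. = FALSE)
  x <- xv / sqrt(sum(xv^2))
  if (sum((gt - origin) * z) < 0) z <- -z
  # re-derive x after a possible z flip: x is perpendicular to z by
  # construction and unaffected by its sign
  y <- c(z[2] * x[3] - z[3] * x[2],
         z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  structure(list(origin = origin, x_axis = x, y_axis = y, z_axis = z,
                 side = side),
            class = "femoral_frame")
}

#' @export
print.femoral_frame <- function(x, ...) {
  cat("Femoral landmark frame", if (!is.null(x$side)) sprintf("(%s)", x$side),
      "\n")
  cat(sprintf("  origin: (%.2f, %.2f, %.2f)\n",
              x$origin[1], x$origin[2], x$origin[3]))
  for (ax in c("x_axis", "y_axis", "z_axis"))
    cat(sprintf("  %s: (%.4f, %.4f, %.4f)\n", ax, x[[ax]][1], x[[ax]][2],
                x[[ax]][3]))
  invisible(x)
}

#' Express a point in a femoral frame
#'
#' Isometric change of coordinates: `((p - O) . x, (p - O) . y, (p - O) . z)`.
#'
#' @param p point (3-vector, mm) in the original coordinates.
#' @param frame a [build_femoral_frame()] result.
#' @return 3-vector of frame coordinates (mm).
#' @export
transform_to_frame <- function(p, frame) {
  stopifnot(inherits(frame, "femoral_frame"))
  v <- check_point3(p, "p") - frame$origin
  c(sum(v * frame$x_axis), sum(v * frame$y_axis), sum(v * frame$z_axis))
}

#' Displacement of an endpoint between two measurements
#'
#' The Euclidean distance between a pin endpoint's coordinates measured at
#' two time points in a common frame — the quantity the traditional manual
#' method reports.
#'
#' @param before,after 3-vectors (mm), or a list/data.frame row with
#'   elements `before` and `after`.
#' @return displacement in mm.
#' @export
displacement_from_coordinates <- function(before, after = NULL) {
  if (is.null(after) && is.list(before)) {
    after <- before$after
    before <- before$before
  }
  euclidean_distance(before, after)
}

#' Relative error of a measured displacement
#'
#' `|measured - reference| / reference * 100`, the percent error of a
#' displacement measurement against a trusted reference value (e.g. the
#' average of repeated manual measurements).
#'
#' @param measured_mm measured displacement.
#' @param reference_mm reference displacement (> 0).
#' @return percent.
#' @export
relative_error_percent <- function(measured_mm, reference_mm) {
  if (any(!is.finite(measured_mm)) || any(!is.finite(reference_mm)))
    stop("inputs must be finite", call. = FALSE)
  if (any(reference_mm <= 0))
    stop("reference displacement must be positive", call. = FALSE)
  abs(measured_mm - reference_mm) / reference_mm * 100
}

#' Traditional-vs-reference comparison table
#'
#' Computes, per pin endpoint, the displacement between two measured
#' coordinate sets and its relative error against a manual reference
#' measurement. Displacements are rounded to 2 decimal places before the
#' relative error is formed, matching how such comparison tables are
#' conventionally reported (all values retained at two decimals).
#'
#' @param endpoints data.frame with columns `label, x1, y1, z1, x2, y2, z2`
#'   (coordinates at the two time points, mm).
#' @param manual_mm optional numeric vector of reference displacements
#'   (same order/length as `endpoints` rows, or named by label).
#' @return data.frame with `label`, `displacement_mm` (2 d.p.) and, when
#'   references are given, `manual_mm` and `relative_error_pct` (2 d.p.).
#' @export
traditional_comparison <- function(endpoints, manual_mm = NULL) {
  req <- c("label", "x1", "y1", "z1", "x2", "y2", "z2")
  if (!all(req %in% names(endpoints)))
    stop("endpoints must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  disp <- vapply(seq_len(nrow(endpoints)), function(i) {
    euclidean_distance(as.numeric(endpoints[i, c("x1", "y1", "z1")]),
                       as.numeric(endpoints[i, c("x2", "y2", "z2")]))
  }, numeric(1))
  out <- data.frame(label = endpoints$label,
                    displacement_mm = round(disp, 2))
  if (!is.null(manual_mm)) {
    if (!is.null(names(manual_mm)))
      manual_mm <- manual_mm[as.character(endpoints$label)]
    if (length(manual_mm) != nrow(out))
      stop("manual_mm must match the endpoint rows", call. = FALSE)
    out$manual_mm <- as.numeric(manual_mm)
    out$relative_error_pct <-
      round(relative_error_percent(out$displacement_mm, out$manual_mm), 2)
  }
  out
}

#' Read picked landmarks from JSON
#'
#' Expected schema:
#' `{"side": "left", "axis_points": [[x,y,z],[x,y,z]],
#'   "lesser_trochanter": [x,y,z], "gt_hint": [x,y,z]}`.
#'
#' @param path JSON file.
#' @return a [build_femoral_frame()] result.
#' @export
read_landmarks <- function(path) {
  lm <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("axis_points", "lesser_trochanter", "gt_hint"))
    if (is.null(lm[[f]]))
      stop("landmark file missing field: ", f, call. = FALSE)
  ap <- lm$axis_points
  if (is.list(ap)) ap <- do.call(rbind, ap)
  build_femoral_frame(ap[1, ], ap[2, ], lm$lesser_trochanter, lm$gt_hint,
                      side = lm$side)
}

#' Read an endpoint coordinate table
#'
#' CSV with columns `label, x1, y1, z1, x2, y2, z2`: each row is one pin
#' endpoint with its coordinates at the two time points in a common frame.
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
read_endpoints <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("label", "x1", "y1", "z1", "x2", "y2", "z2")
  if (!all(req %in% names(df)))
    stop("endpoint CSV must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  if (!all(vapply(df[req[-1]], function(col) all(is.finite(col)), logical(1))))
    stop("endpoint CSV contains non-finite coordinates", call. = FALSE)
  df
}
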