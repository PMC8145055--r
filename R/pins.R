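#' Fit a pin's central axis by principal component analysis
#'
#' The first principal component of the centred cloud (eigenvector of the
#' covariance matrix with the largest eigenvalue) is the direction in which
#' an elongated pin cloud extends. PCA axes are sign-ambiguous, so the
#' returned axis is flipped, if necessary, to have a positive dot product
#' with `top_hint` (a rough direction toward the pin's top; default +z,
#' matching models reconstructed with the shaft roughly along z).
#'
#' @param cloud pin point cloud (>= 3 points, not all coincident).
#' @param top_hint rough 3-vector toward the pin top used to orient the axis.
#' @return list with `axis` (unit 3-vector) and `center` (cloud centroid).
#' @export
fit_pin_axis <- function(cloud, top_hint = c(0, 0, 1)) {
  m <- as_cloud_matrix(cloud)
  if (nrow(m) < 2L)
    stop("need at least 2 points to fit an axis", call. = FALSE)
  ctr <- colMeans(m)
  mc <- sweep(m, 2L, ctr)
  cv <- crossprod(mc) / nrow(m)
  eg <- eigen(cv, symmetric = TRUE)
  if (nrow(m) >= 3L && (eg$values[1] - eg$values[2]) < 1e-9)
    stop("ambiguous axis: cloud has no dominant principal direction", call. = FALSE)
  axis <- eg$vectors[, 1]
  hint <- check_point3(top_hint, "top_hint")
  if (sum(axis * hint) < 0) axis <- -axis
  list(axis = axis / sqrt(sum(axis^2)), center = ctr)
}

#' Endpoints and extent of a pin along its axis
#'
#' Points are projected onto the axis; the extent is the difference between
#' the maximal and minimal projection. Each endpoint lies on the central
#' axis (through the cloud centroid): its off-axis position is the axis
#' line's, and its axial position is the mean projection of the points in a
#' cap slab of width `cap_width_mm` at that extreme, pushed out by half the
#' slab width. Using the cap-slab mean rather than the single extreme point
#' makes the endpoints robust to isolated noise spikes; the half-width
#' offset recenters the estimate on the physical end face.
#'
#' @param cloud pin point cloud.
#' @param axis unit 3-vector (see [fit_pin_axis()]); "top" is the +axis end.
#' @param center point on the axis line (default: cloud centroid).
#' @param cap_width_mm width of the end-cap slab (default 2).
#' @return list with `top`, `bottom` (3-vectors, mm) and `extent_mm`
#'   (max - min projection).
#' @export
compute_obb_endpoints <- function(cloud, axis, center = NULL, cap_width_mm = 2) {
  m <- as_cloud_matrix(cloud)
  axis <- check_point3(axis, "axis")
  if (abs(sqrt(sum(axis^2)) - 1) > 1e-6)
    stop("axis must be a unit vector", call. = FALSE)
  if (is.null(center)) center <- colMeans(m)
  proj <- as.vector(sweep(m, 2L, center) %*% axis)
  hi <- max(proj); lo <- min(proj)
  w <- cap_width_mm
  top_s <- proj >= hi - w
  bot_s <- proj <= lo + w
  s_top <- mean(proj[top_s]) + w / 2
  s_bot <- mean(proj[bot_s]) - w / 2
  # never overshoot the observed extremes
  s_top <- min(s_top, hi); s_bot <- max(s_bot, lo)
  list(top = center + s_top * axis,
       bottom = center + s_bot * axis,
       extent_mm = hi - lo)
}

#' Length scale calibration factor
#'
#' CT-derived models can carry a small global scale error; the known
#' physical length of an implanted pin calibrates it. The returned isotropic
#' factor `nominal / measured` is applied by multiplying all coordinates of
#' the case's clouds.
#'
#' @param measured_length_mm pin length measured from the point cloud.
#' @param nominal_length_mm physical pin length from the implant
#'   specification.
#' @return scale factor (dimensionless, > 0).
#' @export
calibrate_scale <- function(measured_length_mm, nominal_length_mm) {
  if (!is.numeric(measured_length_mm) || measured_length_mm <= 0 ||
      !is.numeric(nominal_length_mm) || nominal_length_mm <= 0)
    stop("lengths must be positive", call. = FALSE)
  nominal_length_mm / measured_length_mm
}

#' Angle between two pin axes
#'
#' Axis directions are unoriented (a PCA axis and its negation describe the
#' same pin), so the relative angle is `acos(|a . b|)`, in \[0, 90\] degrees.
#'
#' @param axis_before,axis_after unit 3-vectors.
#' @return angle in degrees.
#' @export
relative_angle <- function(axis_before, axis_after) {
  a <- check_point3(axis_before, "axis_before")
  b <- check_point3(axis_after, "axis_after")
  if (abs(sqrt(sum(a^2)) - 1) > 1e-6 || abs(sqrt(sum(b^2)) - 1) > 1e-6)
    stop("axes must be unit vectors", call. = FALSE)
  acos(min(1, abs(sum(a * b)))) * 180 / pi
}

#' Estimate the hook direction of a pin cloud
#'
#' A Hansson pin's deployed hook breaks the pin's rotational symmetry near
#' its top. The hook direction is estimated as the direction of maximal mass
#' asymmetry perpendicular to the axis within the top third of the pin: the
#' mean off-axis offset of the outer half of those points (the inner, nearly
#' symmetric core dilutes the signal and is ignored). The estimate assumes
#' an interior-filled ("solid") pin cloud, as produced by filled-model
#' reconstruction; on a hollow surface cloud the outer-half selection is not
#' informative and a user-supplied hint should be preferred.
#'
#' @param cloud pin cloud.
#' @param axis,center fitted axis and centroid (see [fit_pin_axis()]).
#' @return unit 3-vector perpendicular to `axis`.
#' @export
estimate_hook_direction <- function(cloud, axis, center) {
  m <- as_cloud_matrix(cloud)
  axis <- unit3(axis, "axis")
  center <- check_point3(center, "center")
  rel <- sweep(m, 2L, center)
  proj <- as.vector(rel %*% axis)
  top <- proj >= max(proj) - (max(proj) - min(proj)) / 3
  perp <- rel[top, , drop = FALSE] - outer(proj[top], axis)
  r <- sqrt(rowSums(perp^2))
  outer_half <- r >= median(r)
  v <- colMeans(perp[outer_half, , drop = FALSE])
  n <- sqrt(sum(v^2))
  # relative check: a rotationally symmetric cloud has a mean offset that is
  # only sampling noise, far below the typical off-axis radius
  if (n < 0.1 * mean(r))
    stop("hook direction is degenerate: pin cloud is rotationally symmetric",
         call. = FALSE)
  v / n
}

#' Build a pin model from its point cloud
#'
#' Fits the central axis (PCA), extracts endpoints and extent from the
#' oriented bounding box along that axis, measures the pin length as the
#' top-bottom distance, and records the scale factor against the nominal
#' (physical) length. The hook direction is taken from `hook_hint`
#' (projected perpendicular to the axis) when supplied, otherwise estimated
#' from the cloud's mass asymmetry via [estimate_hook_direction()].
#'
#' @param cloud pin point cloud.
#' @param nominal_length_mm physical pin length (e.g. 80 or 90 mm); `NA`
#'   skips calibration (scale factor 1).
#' @param top_hint rough direction toward the pin top (default +z).
#' @param hook_hint optional rough hook direction 3-vector.
#' @param cap_width_mm end-cap slab width for endpoint extraction.
#' @return object of class `"pin_model"`.
#' @export
pin_model <- function(cloud, nominal_length_mm = NA_real_,
                      top_hint = c(0, 0, 1), hook_hint = NULL,
                      cap_width_mm = 2) {
  m <- as_cloud_matrix(cloud)
  ax <- fit_pin_axis(m, top_hint = top_hint)
  ends <- compute_obb_endpoints(m, ax$axis, center = ax$center,
                                cap_width_mm = cap_width_mm)
  measured <- euclidean_distance(ends$top, ends$bottom)
  # calibration uses the axial extent: unlike the slab-based endpoints it is
  # exactly scale-equivariant, so calibrating a calibrated cloud is a no-op
  scale_factor <- if (is.na(nominal_length_mm)) 1
                  else calibrate_scale(ends$extent_mm, nominal_length_mm)
  hook <- if (!is.null(hook_hint)) {
    h <- check_point3(hook_hint, "hook_hint")
    hp <- h - sum(h * ax$axis) * ax$axis
    if (sqrt(sum(hp^2)) < sin(pi / 180))
      stop("degenerate frame: hook_hint within 1 degree of the pin axis",
           call. = FALSE)
    hp / sqrt(sum(hp^2))
  } else {
    estimate_hook_direction(m, ax$axis, ax$center)
  }
  structure(list(cloud = point_cloud(m, label = attr(cloud, "label")),
                 axis = ax$axis, center = ax$center,
                 top = ends$top, bottom = ends$bottom,
                 extent_mm = ends$extent_mm,
                 measured_length_mm = measured,
                 nominal_length_mm = nominal_length_mm,
                 scale_factor = scale_factor,
                 hook_direction = hook),
            class = "pin_model")
}

#' @export
print.pin_model <- function(x, ...) {
  cat("Pin model\n")
  cat(sprintf("  axis: (%.4f, %.4f, %.4f)\n", x$axis[1], x$axis[2], x$axis[3]))
  cat(sprintf("  measured length: %.2f mm (nominal %s mm, scale factor %.4f)\n",
              x$measured_length_mm,
              if (is.na(x$nominal_length_mm)) "?" else
                format(x$nominal_length_mm), x$scale_factor))
  cat(sprintf("  top:    (%.2f, %.2f, %.2f)\n", x$top[1], x$top[2], x$top[3]))
  cat(sprintf("  bottom: (%.2f, %.2f, %.2f)\n", x$bottom[1], x$bottom[2], x$bottom[3]))
  invisible(x)
}

#' Pin-local coordinate frame
#'
#' The pin-local frame used to decompose migration: z is the pin's central
#' axis (toward the top), y is the hook direction orthogonalised against z
#' (positive toward hook elongation), and x is `y` cross `z`. The origin is
#' the pin-cloud centroid. The result is an orthonormal right-handed triad.
#'
#' @param pin a [pin_model()], or a list with `axis`, `hook_direction`,
#'   `center`.
#' @return object of class `"pin_frame"` with `origin`, `x_axis`, `y_axis`,
#'   `z_axis`.
#' @export
build_pin_frame <- function(pin) {
  z <- unit3(pin$axis, "axis")
  h <- check_point3(pin$hook_direction, "hook_direction")
  hp <- h - sum(h * z) * z
  if (sqrt(sum(hp^2)) < sqrt(sum(h^2)) * sin(pi / 180))
    stop("degenerate frame: hook direction within 1 degree of the axis",
         call. = FALSE)
  y <- hp / sqrt(sum(hp^2))
  x <- c(y[2] * z[3] - y[3] * z[2],
         y[3] * z[1] - y[1] * z[3],
         y[1] * z[2] - y[2] * z[1])
  structure(list(origin = check_point3(pin$center, "center"),
                 x_axis = x, y_axis = y, z_axis = z),
            class = "pin_frame")
}

#' Decompose a displacement vector in a pin frame
#'
#' Components are the dot products of the vector with the frame's axes;
#' because the frame is orthonormal the Euclidean norm is preserved, so the
#' per-axis components always recombine to the scalar movement.
#'
#' @param vec displacement 3-vector (mm).
#' @param frame a [build_pin_frame()] result.
#' @return named 3-vector `c(x, y, z)` of components in mm.
#' @export
decompose_displacement <- function(vec, frame) {
  stopifnot(inherits(frame, "pin_frame"))
  v <- check_point3(vec, "vec")
  c(x = sum(v * frame$x_axis), y = sum(v * frame$y_axis),
    z = sum(v * frame$z_axis))
}

#' Endpoint displacement between two epochs of the same pin
#'
#' The follow-up pin must already be mapped into the postoperative
#' coordinate system (via the femur ICP transform). Movement of each
#' endpoint is the Euclidean distance between its two positions. The two
#' pin models must agree on orientation (axes not anti-aligned), otherwise
#' top and bottom would be swapped.
#'
#' @param pin_before postoperative [pin_model()].
#' @param pin_after_transformed follow-up [pin_model()] in the
#'   postoperative frame.
#' @return list with `top_mm` and `bottom_mm`.
#' @export
endpoint_displacement <- function(pin_before, pin_after_transformed) {
  if (sum(pin_before$axis * pin_after_transformed$axis) <= 0)
    stop("pin axes are anti-aligned; resolve endpoint orientation first",
         call. = FALSE)
  list(top_mm = euclidean_distance(pin_before$top, pin_after_transformed$top),
       bottom_mm = euclidean_distance(pin_before$bottom,
                                      pin_after_transformed$bottom))
}
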