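#' Construct a 3D point cloud
#'
#' A point cloud is an N x 3 numeric matrix of coordinates in millimetres,
#' optionally tagged with a free-text role label (e.g. `"femur_ref"`,
#' `"proximal_pin"`). The constructor validates that every coordinate is
#' finite and that at least one point is present.
#'
#' @param points numeric matrix (or coercible) with 3 columns: x, y, z in mm.
#' @param label optional character role tag.
#' @return an object of class `"point_cloud"`: the validated matrix with
#'   columns named x, y, z and a `label` attribute.
#' @examples
#' pc <- point_cloud(matrix(rnorm(30), ncol = 3), label = "demo")
#' nrow(pc)
#' @export
point_cloud <- function(points, label = NULL) {
  if (is.data.frame(points)) points <- as.matrix(points)
  if (is.null(dim(points)) && length(points) == 3L) points <- matrix(points, 1L, 3L)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L)
    stop("point cloud must have 3 columns (x, y, z)", call. = FALSE)
  if (nrow(points) < 1L)
    stop("point cloud must contain at least one point", call. = FALSE)
  if (!all(is.finite(points)))
    stop("point cloud contains non-finite coordinates", call. = FALSE)
  dimnames(points) <- list(NULL, c("x", "y", "z"))
  structure(points, label = label, class = c("point_cloud", "matrix", "array"))
}

#' @export
print.point_cloud <- function(x, ...) {
  lab <- attr(x, "label")
  cat(sprintf("Point cloud%s: %d points (mm)\n",
              if (!is.null(lab)) paste0(" '", lab, "'") else "", nrow(x)))
  ctr <- colMeans(x)
  cat(sprintf("  centroid: (%.2f, %.2f, %.2f)\n", ctr[1], ctr[2], ctr[3]))
  rng <- apply(x, 2, range)
  cat(sprintf("  extent:   x [%.2f, %.2f]  y [%.2f, %.2f]  z [%.2f, %.2f]\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  invisible(x)
}

as_cloud_matrix <- function(cloud) {
  if (inherits(cloud, "point_cloud")) return(unclass_cloud(cloud))
  unclass_cloud(point_cloud(cloud))
}

unclass_cloud <- function(cloud) {
  attr(cloud, "label") <- NULL
  class(cloud) <- NULL
  cloud
}

check_point3 <- function(p, name = "point") {
  p <- as.numeric(p)
  if (length(p) != 3L || !all(is.finite(p)))
    stop(sprintf("%s must be a finite 3-vector", name), call. = FALSE)
  p
}

#' Euclidean distance between two 3D points
#'
#' The straight-line distance
#' \eqn{d = \sqrt{(x_1-x_2)^2 + (y_1-y_2)^2 + (z_1-z_2)^2}}, the basic
#' quantity from which all displacement measurements here derive.
#'
#' @param a,b finite 3-vectors (mm).
#' @return distance in mm.
#' @examples
#' euclidean_distance(c(0, 0, 0), c(3, 4, 0))  # 5
#' @export
euclidean_distance <- function(a, b) {
  a <- check_point3(a, "a"); b <- check_point3(b, "b")
  sqrt(sum((a - b)^2))
}

#' Construct a rigid transform
#'
#' A rigid (Euclidean) transform acting on column vectors as
#' `x -> rotation %*% x + translation`. The rotation must be orthonormal
#' with determinant +1 (a proper rotation, no reflection or scaling).
#'
#' @param rotation 3 x 3 rotation matrix.
#' @param translation 3-vector in mm.
#' @param tol tolerance for the orthonormality / determinant checks.
#' @return an object of class `"rigid_transform"` with elements `rotation`
#'   and `translation`.
#' @seealso [apply_transform()], [compose_transforms()], [invert_transform()]
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            tol = 1e-9) {
  rotation <- as.matrix(rotation)
  storage.mode(rotation) <- "double"
  if (!all(dim(rotation) == c(3L, 3L)) || !all(is.finite(rotation)))
    stop("rotation must be a finite 3x3 matrix", call. = FALSE)
  translation <- check_point3(translation, "translation")
  if (max(abs(crossprod(rotation) - diag(3))) > tol)
    stop("rotation matrix is not orthonormal", call. = FALSE)
  if (abs(det(rotation) - 1) > tol)
    stop("rotation matrix must have determinant +1", call. = FALSE)
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("Rigid transform (x -> R x + t)\n")
  cat(sprintf("  rotation angle: %.4f deg\n", rotation_angle_deg(x$rotation)))
  cat(sprintf("  translation:    (%.4f, %.4f, %.4f) mm\n",
              x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Apply a rigid transform to a point cloud
#'
#' Each point is mapped to `rotation %*% p + translation`; point count and
#' order are preserved, so per-point correspondence survives the transform.
#'
#' @param cloud a [point_cloud()] or N x 3 matrix.
#' @param transform a [rigid_transform()].
#' @return the transformed cloud (same class and label as the input).
#' @export
apply_transform <- function(cloud, transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  m <- as_cloud_matrix(cloud)
  out <- m %*% t(transform$rotation)
  out <- sweep(out, 2L, -transform$translation)
  point_cloud(out, label = attr(cloud, "label"))
}

transform_points <- function(m, transform) {
  sweep(m %*% t(transform$rotation), 2L, -transform$translation)
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `inner` first and `outer`
#' afterwards (`outer` after `inner`, matching function composition on
#' column vectors).
#'
#' @param outer,inner [rigid_transform()] objects.
#' @return a [rigid_transform()].
#' @export
compose_transforms <- function(outer, inner) {
  stopifnot(inherits(outer, "rigid_transform"), inherits(inner, "rigid_transform"))
  R <- outer$rotation %*% inner$rotation
  # re-orthonormalize to stop round-off drifting across long compositions
  s <- svd(R)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) R <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
  rigid_transform(R, as.vector(outer$rotation %*% inner$translation) + outer$translation)
}

#' Invert a rigid transform
#'
#' @param transform a [rigid_transform()].
#' @return the inverse transform: `x -> R' (x - t)`.
#' @export
invert_transform <- function(transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -as.vector(Rt %*% transform$translation))
}

#' Rotation matrix about an axis
#'
#' Rodrigues' formula for the proper rotation of `angle_deg` degrees about
#' the (not necessarily unit) `axis`.
#'
#' @param axis 3-vector giving the rotation axis.
#' @param angle_deg rotation angle in degrees.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  axis <- check_point3(axis, "axis")
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop("rotation axis must be non-zero", call. = FALSE)
  u <- axis / n
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rotation angle of a rotation matrix
#'
#' The magnitude of the rotation, in degrees, recovered from the trace:
#' `acos((tr(R) - 1) / 2)`.
#'
#' @param rotation 3 x 3 rotation matrix (or a [rigid_transform()]).
#' @return angle in degrees, in \[0, 180\].
#' @export
rotation_angle_deg <- function(rotation) {
  if (inherits(rotation, "rigid_transform")) rotation <- rotation$rotation
  cosang <- (sum(diag(rotation)) - 1) / 2
  acos(max(-1, min(1, cosang))) * 180 / pi
}

#' Discrepancy between two rigid transforms
#'
#' Measures how far `transform` is from `target` as the rotation angle of the
#' composed residual `transform %*% target^{-1}` and the displacement this
#' residual induces at a reference location (by default the origin; pass the
#' cloud the transforms act on to measure the error where it matters).
#'
#' @param transform,target [rigid_transform()] objects.
#' @param at optional point cloud / matrix of locations at which to evaluate
#'   the residual displacement; the centroid is used.
#' @return list with `angle_deg` and `translation_mm`.
#' @export
transform_discrepancy <- function(transform, target, at = NULL) {
  resid <- compose_transforms(transform, invert_transform(target))
  p <- if (is.null(at)) c(0, 0, 0) else colMeans(as_cloud_matrix(at))
  moved <- as.vector(resid$rotation %*% p) + resid$translation
  list(angle_deg = rotation_angle_deg(resid$rotation),
       translation_mm = sqrt(sum((moved - p)^2)))
}

unit3 <- function(v, name = "vector") {
  v <- check_point3(v, name)
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop(sprintf("%s has zero length", name), call. = FALSE)
  v / n
}
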