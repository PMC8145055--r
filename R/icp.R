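#' Control parameters for ICP registration
#'
#' @param max_iterations iteration cap. The default 125 reflects the point
#'   past which fine-registration accuracy of partial-femur references is
#'   observed to plateau.
#' @param cost_tolerance relative change in the mean-squared correspondence
#'   cost below which iteration stops. Set to 0 to force `max_iterations`
#'   full iterations.
#' @param rejection_angle_deg correspondence pairs whose local outward
#'   directions disagree by more than this angle (degrees) are discarded.
#' @param max_pair_distance_mm optional hard cap on correspondence distance;
#'   `NULL` (default) disables it.
#' @param use_rejection logical; enable correspondence rejection (the
#'   direction-vector threshold plus an adaptive distance gate at 3x the
#'   median pair distance, guarding against segmentation artifacts).
#' @param direction_k neighbourhood size for the local outward-direction
#'   estimate.
#' @return a list of class `"icp_control"`.
#' @export
icp_control <- function(max_iterations = 125L, cost_tolerance = 1e-6,
                        rejection_angle_deg = 60, max_pair_distance_mm = NULL,
                        use_rejection = TRUE, direction_k = 10L) {
  max_iterations <- as.integer(max_iterations)
  if (is.na(max_iterations) || max_iterations < 1L)
    stop("max_iterations must be >= 1", call. = FALSE)
  if (!is.numeric(cost_tolerance) || cost_tolerance < 0)
    stop("cost_tolerance must be >= 0", call. = FALSE)
  if (!is.numeric(rejection_angle_deg) ||
      rejection_angle_deg <= 0 || rejection_angle_deg > 180)
    stop("rejection_angle_deg must be in (0, 180]", call. = FALSE)
  if (!is.null(max_pair_distance_mm) && max_pair_distance_mm <= 0)
    stop("max_pair_distance_mm must be positive or NULL", call. = FALSE)
  structure(list(max_iterations = max_iterations,
                 cost_tolerance = cost_tolerance,
                 rejection_angle_deg = rejection_angle_deg,
                 max_pair_distance_mm = max_pair_distance_mm,
                 use_rejection = isTRUE(use_rejection),
                 direction_k = as.integer(direction_k)),
            class = "icp_control")
}

#' Nearest neighbours between point clouds
#'
#' kd-tree nearest-neighbour lookup of each `query` point in `reference`,
#' with ties broken toward the lowest reference index.
#'
#' @param reference,query point clouds or N x 3 matrices.
#' @param k number of neighbours (default 1).
#' @return for `k = 1` a list with `index` and `distance` vectors; otherwise
#'   N x k matrices.
#' @export
nearest_neighbours <- function(reference, query, k = 1L) {
  ref <- as_cloud_matrix(reference)
  qry <- as_cloud_matrix(query)
  if (k == 1L) cpp_nearest(ref, qry) else cpp_knearest(ref, qry, as.integer(k))
}

#' Local outward direction vectors
#'
#' For each point, the unit vector from the centroid of its k nearest
#' neighbours (within the same cloud, excluding the point itself) to the
#' point. On interior-filled ("solid") clouds this points outward from the
#' local mass and is used to veto implausible ICP correspondences. Points in
#' locally symmetric neighbourhoods get a near-zero raw vector; these are
#' returned as zero rows and treated as "no opinion" during rejection.
#'
#' @param cloud a point cloud or N x 3 matrix.
#' @param k neighbourhood size (default 10); the cloud must have more than
#'   `k` points.
#' @return N x 3 matrix of unit (or zero) direction vectors.
#' @export
local_directions <- function(cloud, k = 10L) {
  m <- as_cloud_matrix(cloud)
  n <- nrow(m)
  if (n <= k)
    stop(sprintf("cloud has %d points; need more than k = %d for direction estimation",
                 n, k), call. = FALSE)
  nb <- cpp_knearest(m, m, as.integer(k) + 1L)
  idx <- nb$index
  dirs <- matrix(0, n, 3L)
  for (i in seq_len(n)) {
    row <- idx[i, ]
    self <- match(i, row)
    row <- if (is.na(self)) row[-(k + 1L)] else row[-self]
    ctr <- colMeans(m[row, , drop = FALSE])
    v <- m[i, ] - ctr
    nv <- sqrt(sum(v^2))
    if (nv > 1e-9) dirs[i, ] <- v / nv
  }
  dirs
}

#' Initial centroid alignment
#'
#' The translation `t0 = centroid(Q) - centroid(P)` that moves the cloud to
#' be matched (`P`) so its centroid coincides with the reference (`Q`) — the
#' starting point of the fine registration.
#'
#' @param P cloud to be matched; @param Q reference cloud.
#' @return translation 3-vector (mm).
#' @export
center_align <- function(P, Q) {
  colMeans(as_cloud_matrix(Q)) - colMeans(as_cloud_matrix(P))
}

#' Find ICP correspondences
#'
#' Pairs each point of `P` with its nearest point of `Q`. With rejection
#' enabled, a pair is discarded when the angle between the two points' local
#' outward directions exceeds `rejection_angle_deg` (pairs where either
#' direction is degenerate are kept), when its distance exceeds
#' `max_pair_distance_mm` (if set), or when its distance exceeds 3x the
#' median pair distance (adaptive trimming of gross outliers).
#'
#' @param P,Q point clouds.
#' @param control an [icp_control()].
#' @param directions_P,directions_Q optional precomputed N x 3 direction
#'   matrices (see [local_directions()]); computed on the fly if omitted and
#'   rejection is enabled.
#' @return list of class `"correspondence_set"`: `pairs` (data.frame with
#'   `ip`, `iq`, `distance`), `n_accepted`, `n_rejected`.
#' @export
find_correspondences <- function(P, Q, control = icp_control(),
                                 directions_P = NULL, directions_Q = NULL) {
  Pm <- as_cloud_matrix(P); Qm <- as_cloud_matrix(Q)
  nn <- cpp_nearest(Qm, Pm)
  keep <- rep(TRUE, nrow(Pm))
  if (control$use_rejection) {
    if (is.null(directions_P)) directions_P <- local_directions(Pm, control$direction_k)
    if (is.null(directions_Q)) directions_Q <- local_directions(Qm, control$direction_k)
    dq <- directions_Q[nn$index, , drop = FALSE]
    dots <- rowSums(directions_P * dq)
    # zero rows have dot 0 but also norm 0: identify true degenerates
    degen <- rowSums(directions_P^2) < 0.5 | rowSums(dq^2) < 0.5
    cos_thresh <- cos(control$rejection_angle_deg * pi / 180)
    keep <- degen | (dots >= cos_thresh)
    med <- median(nn$distance)
    keep <- keep & (nn$distance <= 3 * med + 1e-9)
  }
  if (!is.null(control$max_pair_distance_mm))
    keep <- keep & (nn$distance <= control$max_pair_distance_mm)
  pairs <- data.frame(ip = which(keep), iq = nn$index[keep],
                      distance = nn$distance[keep])
  structure(list(pairs = pairs,
                 n_accepted = nrow(pairs),
                 n_rejected = nrow(Pm) - nrow(pairs)),
            class = "correspondence_set")
}

#' Estimate the least-squares rigid update for a correspondence set
#'
#' The rigid transform minimising the mean squared distance between paired
#' points, obtained in closed form from the SVD of the cross-covariance of
#' the centred pairs (Kabsch), with the determinant-corrected solution so a
#' reflection is never returned.
#'
#' @param correspondences a correspondence set from [find_correspondences()],
#'   or a data.frame with columns `ip` and `iq`.
#' @param P,Q the point clouds the pair indices refer to.
#' @return a [rigid_transform()] mapping P onto Q.
#' @export
estimate_rigid_update <- function(correspondences, P, Q) {
  pairs <- if (inherits(correspondences, "correspondence_set"))
    correspondences$pairs else as.data.frame(correspondences)
  Pm <- as_cloud_matrix(P); Qm <- as_cloud_matrix(Q)
  if (nrow(pairs) < 3L)
    stop("degenerate geometry: need at least 3 correspondence pairs", call. = FALSE)
  A <- Pm[pairs$ip, , drop = FALSE]
  B <- Qm[pairs$iq, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2L, ca); Bc <- sweep(B, 2L, cb)
  H <- crossprod(Ac, Bc)
  s <- svd(H)
  spreadA <- svd(Ac, nu = 0, nv = 0)$d
  if (spreadA[2] < 1e-9 * max(spreadA[1], 1))
    stop("degenerate geometry: correspondence points are collinear", call. = FALSE)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rigid_transform(R, cb - as.vector(R %*% ca), tol = 1e-6)
}

#' Iterative closest point registration
#'
#' Fits the rigid transform aligning the cloud to be matched (`P`, e.g. the
#' follow-up partial femur) onto the fixed reference (`Q`, the postoperative
#' partial femur). Starting from the centroid-aligning translation, the
#' algorithm alternates nearest-neighbour correspondence search (with
#' optional rejection of implausible pairs) and the closed-form least-squares
#' rigid update, accumulating the per-iteration updates into one total
#' transform. Iteration stops when the relative change in the mean-squared
#' correspondence cost falls below `cost_tolerance`, or at `max_iterations`.
#'
#' Inputs are assumed roughly pre-oriented (within about 20 degrees), as is
#' the case when both models are reconstructed with the same initial
#' orientation; no global rotational pre-alignment is attempted.
#'
#' @param P cloud to be matched (moves).
#' @param Q reference cloud (fixed).
#' @param control an [icp_control()].
#' @return an object of class `"icp"` with elements `transform` (total
#'   [rigid_transform()]), `initial_translation` (t0), `cost_trace`
#'   (mean-squared pair distance, mm^2, one entry per iteration),
#'   `iterations_run`, `converged`, `n_accepted`, `n_rejected`, and the
#'   input sizes. Standard methods are available: `print`, `summary`,
#'   `coef` (3 x 4 matrix `[R | t]`), `predict` (apply the fitted transform
#'   to a cloud), `fitted`, `residuals` (nearest-neighbour distances of the
#'   registered cloud to the reference), `plot` (cost trace).
#' @examples
#' ph <- generate_phantom(phantom_spec(seed = 1, noise_sd_mm = 0,
#'                                     outlier_fraction = 0))
#' fit <- icp(ph$followup$femur_ref, ph$postop$femur_ref)
#' fit
#' @export
icp <- function(P, Q, control = icp_control()) {
  Pm <- as_cloud_matrix(P); Qm <- as_cloud_matrix(Q)
  if (nrow(Pm) < 3L || nrow(Qm) < 3L)
    stop("both clouds need at least 3 points", call. = FALSE)

  t0 <- center_align(Pm, Qm)
  total <- rigid_transform(diag(3), t0)
  cur <- sweep(Pm, 2L, -t0)

  dirQ <- NULL; dirP0 <- NULL
  if (control$use_rejection) {
    dirQ <- local_directions(Qm, control$direction_k)
    dirP0 <- local_directions(Pm, control$direction_k)
  }

  cost_trace <- numeric(0)
  converged <- FALSE
  n_acc <- NA_integer_; n_rej <- NA_integer_

  for (it in seq_len(control$max_iterations)) {
    dirP <- if (is.null(dirP0)) NULL else dirP0 %*% t(total$rotation)
    cs <- find_correspondences(cur, Qm, control,
                               directions_P = dirP, directions_Q = dirQ)
    if (cs$n_accepted < 3L)
      stop("degenerate geometry: fewer than 3 accepted correspondences", call. = FALSE)
    E <- mean(cs$pairs$distance^2)
    if (!is.finite(E))
      stop("numerical failure: non-finite registration cost", call. = FALSE)
    cost_trace <- c(cost_trace, E)
    n_acc <- cs$n_accepted; n_rej <- cs$n_rejected
    if (it > 1L && control$cost_tolerance > 0) {
      prev <- cost_trace[it - 1L]
      if (abs(E - prev) <= control$cost_tolerance * max(prev, .Machine$double.eps)) {
        converged <- TRUE
        break
      }
    }
    upd <- estimate_rigid_update(cs, cur, Qm)
    cur <- transform_points(cur, upd)
    total <- compose_transforms(upd, total)
  }

  structure(list(transform = total,
                 initial_translation = t0,
                 cost_trace = cost_trace,
                 iterations_run = length(cost_trace),
                 converged = converged,
                 n_accepted = n_acc,
                 n_rejected = n_rej,
                 n_P = nrow(Pm), n_Q = nrow(Qm),
                 control = control,
                 P = Pm, Q = Qm,
                 call = match.call()),
            class = "icp")
}

#' @export
print.icp <- function(x, ...) {
  cat("ICP rigid registration\n")
  cat(sprintf("  %d points matched onto %d reference points\n", x$n_P, x$n_Q))
  cat(sprintf("  iterations: %d (%s)\n", x$iterations_run,
              if (x$converged) "converged" else "iteration cap reached"))
  cat(sprintf("  final cost E: %.6g mm^2 over %d accepted pairs (%d rejected)\n",
              x$cost_trace[x$iterations_run], x$n_accepted, x$n_rejected))
  print(x$transform)
  invisible(x)
}

#' @export
summary.icp <- function(object, thresholds = c(0.5, 2), ...) {
  q <- registration_quality(fitted(object), object$Q, thresholds = thresholds)
  out <- list(fit = object, quality = q)
  class(out) <- "summary.icp"
  out
}

#' @export
print.summary.icp <- function(x, ...) {
  print(x$fit)
  cat("\nRegistration quality (registered cloud -> reference):\n")
  print(x$quality)
  invisible(x)
}

#' @export
coef.icp <- function(object, ...) {
  cbind(object$transform$rotation, t = object$transform$translation)
}

#' @export
predict.icp <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  apply_transform(newdata, object$transform)
}

#' @export
fitted.icp <- function(object, ...) {
  point_cloud(transform_points(object$P, object$transform), label = "registered")
}

#' @export
residuals.icp <- function(object, ...) {
  cpp_nearest(object$Q, transform_points(object$P, object$transform))$distance
}

#' @export
plot.icp <- function(x, ...) {
  plot(seq_along(x$cost_trace), x$cost_trace, type = "b", log = "y",
       xlab = "iteration", ylab = expression(E ~ (mm^2)),
       main = "ICP cost trace", ...)
  invisible(x)
}
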