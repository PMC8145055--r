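# Seeded generator of femur + pin phantoms with known ground truth.
# Patient CT data are not distributable, so validation runs on these
# synthetic stand-ins: a solid tube with a trochanteric bump (the cropped
# partial-femur reference, interior filled) and two cylindrical pins with a
# hook fin breaking rotational symmetry.

local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of a synthetic femur + pin phantom
#'
#' Defines the geometry, migration, and corruption parameters of one
#' synthetic case. Defaults emulate the study conditions of a typical
#' Hansson-pin fixation: a 6.5 mm diameter pin pair (radius 3.25 mm) with
#' nominal lengths 80 and 90 mm inserted at 45 degrees through the
#' trochanteric region; a partial-femur reference of about 2000 points with
#' 0.3 mm Gaussian surface noise and 5% outlier points emulating
#' threshold-segmentation artifacts; and a modest downward (negative axial)
#' pin migration with a small tilt, the motion pattern observed clinically.
#'
#' @param n_femur_points,n_pin_points cloud sizes (>= 10).
#' @param femur_length_mm,femur_radius_mm tube geometry of the cropped
#'   reference.
#' @param bump_offset_mm radial offset of the trochanteric bump's centre
#'   from the shaft axis (the bump removes rotational symmetry).
#' @param bump_radius_mm bump radius.
#' @param pins list of two pin specs (`proximal`, `distal`), each with
#'   `length_mm`, `radius_mm`, `center` (3-vector), and optionally
#'   `insertion_angle_deg` (tilt of the pin axis from the shaft z-axis).
#' @param hook_height_mm radial protrusion of the hook fin.
#' @param hook_fraction fraction of pin points allocated to the hook fin.
#' @param noise_sd_mm standard deviation of the iid Gaussian surface noise
#'   added to the follow-up clouds.
#' @param outlier_fraction fraction (of femur points, in \[0, 0.5)) of
#'   outlier points appended to the follow-up femur cloud, sampled in a
#'   2-20 mm shell around the surface.
#' @param global_transform optional [rigid_transform()]: the follow-up
#'   scanner pose relative to the postoperative one. `NULL` samples a
#'   rotation of 3-10 degrees about a random axis and a translation
#'   uniform in \[-10, 10\] mm per component.
#' @param migrations optional list with `proximal` and `distal`, each
#'   `list(axial_mm =, tilt_deg =)`: signed axial translation along the pin
#'   axis and tilt about a random axis through the pin centre.
#' @param seed integer seed; the phantom is bit-reproducible given the spec.
#' @return a validated list of class `"phantom_spec"`.
#' @export
phantom_spec <- function(n_femur_points = 2000L, n_pin_points = 1200L,
                         femur_length_mm = 120, femur_radius_mm = 15,
                         bump_offset_mm = 15, bump_radius_mm = 12,
                         pins = list(
                           proximal = list(length_mm = 80, radius_mm = 3.25,
                                           center = c(0, 7, 98),
                                           insertion_angle_deg = 45),
                           distal = list(length_mm = 90, radius_mm = 3.25,
                                         center = c(0, -7, 84),
                                         insertion_angle_deg = 45)),
                         hook_height_mm = 4, hook_fraction = 0.15,
                         noise_sd_mm = 0.3, outlier_fraction = 0.05,
                         global_transform = NULL,
                         migrations = list(
                           proximal = list(axial_mm = -5, tilt_deg = 2.5),
                           distal = list(axial_mm = -4, tilt_deg = 2)),
                         seed = 1L) {
  spec <- list(n_femur_points = as.integer(n_femur_points),
               n_pin_points = as.integer(n_pin_points),
               femur_length_mm = femur_length_mm,
               femur_radius_mm = femur_radius_mm,
               bump_offset_mm = bump_offset_mm,
               bump_radius_mm = bump_radius_mm,
               pins = pins, hook_height_mm = hook_height_mm,
               hook_fraction = hook_fraction,
               noise_sd_mm = noise_sd_mm,
               outlier_fraction = outlier_fraction,
               global_transform = global_transform,
               migrations = migrations,
               seed = as.integer(seed))
  if (spec$n_femur_points < 10L || spec$n_pin_points < 10L)
    stop("point counts must be >= 10", call. = FALSE)
  if (femur_length_mm <= 0 || femur_radius_mm <= 0)
    stop("femur dimensions must be positive", call. = FALSE)
  for (p in pins)
    if (p$length_mm <= 0 || p$radius_mm <= 0)
      stop("pin dimensions must be positive", call. = FALSE)
  if (noise_sd_mm < 0) stop("noise_sd_mm must be >= 0", call. = FALSE)
  if (outlier_fraction < 0 || outlier_fraction >= 0.5)
    stop("outlier_fraction must be in [0, 0.5)", call. = FALSE)
  if (!is.null(global_transform) &&
      !inherits(global_transform, "rigid_transform"))
    stop("global_transform must be a rigid_transform or NULL", call. = FALSE)
  structure(spec, class = "phantom_spec")
}

# orthonormal basis perpendicular to unit vector u (deterministic)
perp_basis <- function(u) {
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

sample_femur <- function(spec) {
  n <- spec$n_femur_points
  n_bump <- round(0.2 * n)
  n_tube <- n - n_bump
  z <- runif(n_tube, 0, spec$femur_length_mm)
  r <- spec$femur_radius_mm * sqrt(runif(n_tube))
  th <- runif(n_tube, 0, 2 * pi)
  tube <- cbind(r * cos(th), r * sin(th), z)
  # solid bump on the +x side near the top (greater trochanter analogue)
  ctr <- c(spec$bump_offset_mm, 0, spec$femur_length_mm - spec$bump_radius_mm)
  pts <- matrix(numeric(0), 0, 3)
  while (nrow(pts) < n_bump) {
    m <- matrix(runif(3 * 2 * n_bump, -1, 1), ncol = 3)
    m <- m[rowSums(m^2) <= 1 & m[, 1] >= 0, , drop = FALSE]
    pts <- rbind(pts, m)
  }
  bump <- sweep(pts[seq_len(n_bump), , drop = FALSE] * spec$bump_radius_mm,
                2L, -ctr)
  rbind(tube, bump)
}

sample_pin <- function(spec, pin) {
  n <- spec$n_pin_points
  n_hook <- round(spec$hook_fraction * n)
  n_shaft <- n - n_hook
  L <- pin$length_mm; R <- pin$radius_mm
  z <- runif(n_shaft, -L / 2, L / 2)
  r <- R * sqrt(runif(n_shaft))
  th <- runif(n_shaft, 0, 2 * pi)
  shaft <- cbind(r * cos(th), r * sin(th), z)
  # hook fin: top third, +local-x side, protruding radially
  hz <- runif(n_hook, L / 6, L / 2)
  hth <- runif(n_hook, -20, 20) * pi / 180
  hr <- R + spec$hook_height_mm * runif(n_hook)
  hook <- cbind(hr * cos(hth), hr * sin(hth), hz)
  local <- rbind(shaft, hook)
  ang <- (pin$insertion_angle_deg %||% 45) * pi / 180
  u <- c(sin(ang), 0, cos(ang))
  b <- perp_basis(u)
  world <- local[, 1, drop = FALSE] %*% t(b$e1) +
           local[, 2, drop = FALSE] %*% t(b$e2) +
           local[, 3, drop = FALSE] %*% t(u)
  list(points = sweep(world, 2L, -pin$center),
       axis = u, hook = b$e1, center = pin$center)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

migration_transform <- function(center, axis, axial_mm, tilt_deg, tilt_axis) {
  Rt <- rotation_about_axis(tilt_axis, tilt_deg)
  t <- center - as.vector(Rt %*% center) + axial_mm * axis
  rigid_transform(Rt, t)
}

#' Generate a synthetic femur + pin phantom
#'
#' Builds one case: postoperative clouds (noiseless geometry), follow-up
#' clouds obtained by applying the per-pin migration then the global rigid
#' transform (the change of scanner pose), then Gaussian noise and, for the
#' femur, appended outlier points. The full ground truth is recorded so
#' recovered transforms and migrations can be scored exactly.
#'
#' @param spec a [phantom_spec()].
#' @return a list of class `"phantom_dataset"`: `postop` and `followup`
#'   (each `femur_ref`, `proximal_pin`, `distal_pin` point clouds), and
#'   `truth` (global transform, per-pin migration transforms, analytic
#'   endpoint positions/displacements, relative angles, displacement
#'   components in the true postoperative pin frames, noiseless follow-up
#'   clouds, and per-pin axis/hook/length records).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  local_seed(spec$seed, {
    femur0 <- sample_femur(spec)
    pins0 <- lapply(spec$pins, function(p) sample_pin(spec, p))

    G <- spec$global_transform
    if (is.null(G)) {
      ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
      ang <- runif(1, 3, 10)
      G <- rigid_transform(rotation_about_axis(ax, ang), runif(3, -10, 10))
    }

    truth_pins <- list()
    followup_pins <- list()
    for (nm in names(pins0)) {
      p <- pins0[[nm]]
      mig <- spec$migrations[[nm]] %||% list(axial_mm = 0, tilt_deg = 0)
      phi <- runif(1, 0, 2 * pi)
      b <- perp_basis(p$axis)
      tilt_axis <- cos(phi) * b$e1 + sin(phi) * b$e2
      M <- migration_transform(p$center, p$axis, mig$axial_mm, mig$tilt_deg,
                               tilt_axis)
      L <- spec$pins[[nm]]$length_mm
      top0 <- p$center + L / 2 * p$axis
      bot0 <- p$center - L / 2 * p$axis
      top1 <- as.vector(M$rotation %*% top0) + M$translation
      bot1 <- as.vector(M$rotation %*% bot0) + M$translation
      frame <- build_pin_frame(list(axis = p$axis, hook_direction = p$hook,
                                    center = p$center))
      migrated <- transform_points(p$points, M)
      followup_pins[[nm]] <- transform_points(migrated, G)
      truth_pins[[nm]] <- list(
        migration = M,
        axis = p$axis, hook_direction = p$hook, center = p$center,
        nominal_length_mm = L,
        tilt_deg = mig$tilt_deg, axial_mm = mig$axial_mm,
        top_postop = top0, bottom_postop = bot0,
        top_migrated = top1, bottom_migrated = bot1,
        top_displacement_mm = euclidean_distance(top0, top1),
        bottom_displacement_mm = euclidean_distance(bot0, bot1),
        relative_angle_deg = relative_angle(
          p$axis, as.vector(M$rotation %*% p$axis)),
        top_components_mm = decompose_displacement(top1 - top0, frame),
        bottom_components_mm = decompose_displacement(bot1 - bot0, frame))
    }

    followup_femur <- transform_points(femur0, G)
    noiseless <- list(
      femur_ref = point_cloud(followup_femur, label = "femur_ref"),
      proximal_pin = point_cloud(followup_pins$proximal, label = "proximal_pin"),
      distal_pin = point_cloud(followup_pins$distal, label = "distal_pin"))

    add_noise <- function(m) {
      if (spec$noise_sd_mm > 0)
        m + matrix(rnorm(length(m), 0, spec$noise_sd_mm), nrow(m), 3)
      else m
    }
    followup_femur <- add_noise(followup_femur)
    followup_pins <- lapply(followup_pins, add_noise)

    n_out <- round(spec$outlier_fraction * spec$n_femur_points)
    if (n_out > 0) {
      base <- followup_femur[sample.int(nrow(followup_femur), n_out,
                                        replace = TRUE), , drop = FALSE]
      dir <- matrix(rnorm(3 * n_out), n_out, 3)
      dir <- dir / sqrt(rowSums(dir^2))
      followup_femur <- rbind(followup_femur,
                              base + dir * runif(n_out, 2, 20))
    }

    structure(list(
      spec = spec,
      postop = list(
        femur_ref = point_cloud(femur0, label = "femur_ref"),
        proximal_pin = point_cloud(pins0$proximal$points, label = "proximal_pin"),
        distal_pin = point_cloud(pins0$distal$points, label = "distal_pin")),
      followup = list(
        femur_ref = point_cloud(followup_femur, label = "femur_ref"),
        proximal_pin = point_cloud(followup_pins$proximal, label = "proximal_pin"),
        distal_pin = point_cloud(followup_pins$distal, label = "distal_pin")),
      truth = list(global_transform = G,
                   pins = truth_pins,
                   noiseless_followup = noiseless)),
      class = "phantom_dataset")
  })
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cat("Synthetic femur + pin phantom (seed", x$spec$seed, ")\n")
  cat(sprintf("  femur: %d points (+%d follow-up outliers), pins: %d points each\n",
              x$spec$n_femur_points,
              nrow(x$followup$femur_ref) - x$spec$n_femur_points,
              x$spec$n_pin_points))
  cat(sprintf("  global pose change: %.2f deg / (%.1f, %.1f, %.1f) mm\n",
              rotation_angle_deg(x$truth$global_transform$rotation),
              x$truth$global_transform$translation[1],
              x$truth$global_transform$translation[2],
              x$truth$global_transform$translation[3]))
  for (nm in names(x$truth$pins)) {
    p <- x$truth$pins[[nm]]
    cat(sprintf("  %s pin: axial %.1f mm, tilt %.1f deg (top moves %.2f mm)\n",
                nm, p$axial_mm, p$tilt_deg, p$top_displacement_mm))
  }
  invisible(x)
}

#' Generate a suite of regression phantoms
#'
#' Emulates a 10-case study design: each case gets an independently sampled
#' scanner pose change and per-pin migrations drawn from clinically observed
#' ranges (relative angles roughly 0.5-8 degrees from the tilt plus axial
#' translations of 1-15 mm, giving endpoint movements of about 1-21 mm).
#'
#' @param n_cases number of cases (>= 1).
#' @param seed master seed; each case derives its own stream.
#' @param ... overrides passed to [phantom_spec()] (e.g. `noise_sd_mm`).
#' @return list of [generate_phantom()] datasets.
#' @export
regression_suite <- function(n_cases = 10L, seed = 1L, ...) {
  n_cases <- as.integer(n_cases)
  if (n_cases < 1L) stop("n_cases must be >= 1", call. = FALSE)
  seed <- as.integer(seed)
  params <- local_seed(seed, {
    lapply(seq_len(n_cases), function(i) {
      list(migrations = list(
        proximal = list(axial_mm = -runif(1, 1, 15),
                        tilt_deg = runif(1, 0.5, 8)),
        distal = list(axial_mm = -runif(1, 1, 15),
                      tilt_deg = runif(1, 0.5, 8))),
        case_seed = (seed %% 100000L) * 10000L + i)
    })
  })
  lapply(params, function(pr) {
    generate_phantom(phantom_spec(migrations = pr$migrations,
                                  seed = pr$case_seed, ...))
  })
}
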