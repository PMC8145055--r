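#' Measure pin migration for one case
#'
#' The full measurement pipeline. Both epochs' clouds are first scale
#' calibrated against the known physical pin lengths (isotropic factor per
#' epoch, the mean over the case's pins). The follow-up partial femur is
#' then registered onto the postoperative one with [icp()]; the fitted
#' rigid transform is applied to the follow-up pin clouds, bringing both
#' epochs into the postoperative coordinate system. Each pin's central
#' axis, endpoints, and hook direction are extracted; migration is reported
#' as the relative angle between the two axes, the Euclidean movement of
#' the top and bottom endpoints, and the endpoint displacement vectors
#' decomposed in the postoperative pin-local frame (z along the pin axis
#' toward the top, y toward hook elongation, x = y cross z).
#'
#' @param postop,followup lists with elements `femur_ref`, `proximal_pin`,
#'   `distal_pin` (point clouds), or a `"case_bundle"` from
#'   [read_case_bundle()] passed as `postop` alone.
#' @param pin_lengths named numeric vector `c(proximal =, distal =)` of
#'   physical pin lengths in mm (`NA` disables calibration).
#' @param hook_hints optional list with `proximal`/`distal` rough hook
#'   direction 3-vectors (postoperative frame); estimated from the clouds
#'   when omitted.
#' @param top_hint rough direction toward the pin tops (default +z).
#' @param control an [icp_control()].
#' @param calibrate logical; apply length-scale calibration.
#' @param thresholds quality thresholds in mm.
#' @param case_id identifier carried into reports.
#' @return object of class `"pin_migration"`: `icp` (the femur fit),
#'   `quality`, `pins` (per-pin measurements and models), `scale_factors`,
#'   `summary_table`, `component_table`.
#' @examples
#' ph <- generate_phantom(phantom_spec(seed = 3))
#' rep <- pin_migration(ph$postop, ph$followup)
#' rep
#' @export
pin_migration <- function(postop, followup = NULL,
                          pin_lengths = c(proximal = 80, distal = 90),
                          hook_hints = NULL, top_hint = c(0, 0, 1),
                          control = icp_control(), calibrate = TRUE,
                          thresholds = c(0.5, 2), case_id = "case") {
  if (inherits(postop, "case_bundle")) {
    bundle <- postop
    followup <- bundle$followup
    pin_lengths <- c(proximal = bundle$pins$proximal$length_mm,
                     distal = bundle$pins$distal$length_mm)
    hook_hints <- Filter(Negate(is.null),
                         list(proximal = bundle$pins$proximal$hook_hint,
                              distal = bundle$pins$distal$hook_hint))
    if (length(hook_hints) == 0L) hook_hints <- NULL
    case_id <- bundle$case_id
    postop <- bundle$postop
  }
  roles <- c("femur_ref", "proximal_pin", "distal_pin")
  for (ep in list(postop, followup))
    if (!all(roles %in% names(ep)))
      stop("each epoch needs clouds: ", paste(roles, collapse = ", "),
           call. = FALSE)

  scale_factors <- c(postop = 1, followup = 1)
  epochs <- list(postop = postop, followup = followup)
  if (calibrate && any(!is.na(pin_lengths))) {
    for (ep in names(epochs)) {
      factors <- c()
      for (pn in c("proximal", "distal")) {
        nominal <- pin_lengths[[pn]]
        if (is.na(nominal)) next
        ax <- fit_pin_axis(epochs[[ep]][[paste0(pn, "_pin")]],
                           top_hint = top_hint)
        ends <- compute_obb_endpoints(epochs[[ep]][[paste0(pn, "_pin")]],
                                      ax$axis, center = ax$center)
        factors <- c(factors, calibrate_scale(ends$extent_mm, nominal))
      }
      f <- mean(factors)
      scale_factors[[ep]] <- f
      epochs[[ep]] <- lapply(epochs[[ep]], function(cl)
        point_cloud(as_cloud_matrix(cl) * f, label = attr(cl, "label")))
    }
  }

  fit <- icp(epochs$followup$femur_ref, epochs$postop$femur_ref,
             control = control)
  registered_femur <- fitted(fit)
  quality <- registration_quality(registered_femur,
                                  epochs$postop$femur_ref,
                                  thresholds = thresholds)

  pins <- list()
  for (pn in c("proximal", "distal")) {
    role <- paste0(pn, "_pin")
    hint <- if (!is.null(hook_hints)) hook_hints[[pn]] else NULL
    before <- pin_model(epochs$postop[[role]],
                        nominal_length_mm = pin_lengths[[pn]],
                        top_hint = top_hint, hook_hint = hint)
    after_cloud <- apply_transform(epochs$followup[[role]], fit$transform)
    after <- pin_model(after_cloud,
                       nominal_length_mm = pin_lengths[[pn]],
                       top_hint = before$axis,
                       hook_hint = before$hook_direction)
    frame <- build_pin_frame(before)
    moves <- endpoint_displacement(before, after)
    pins[[pn]] <- list(
      before = before, after = after, frame = frame,
      relative_angle_deg = relative_angle(before$axis, after$axis),
      top_movement_mm = moves$top_mm,
      bottom_movement_mm = moves$bottom_mm,
      top_components_mm = decompose_displacement(after$top - before$top,
                                                 frame),
      bottom_components_mm = decompose_displacement(after$bottom - before$bottom,
                                                    frame))
  }

  summary_table <- data.frame(
    pin = names(pins),
    relative_angle_deg = vapply(pins, `[[`, numeric(1), "relative_angle_deg"),
    top_movement_mm = vapply(pins, `[[`, numeric(1), "top_movement_mm"),
    bottom_movement_mm = vapply(pins, `[[`, numeric(1), "bottom_movement_mm"),
    row.names = NULL)
  component_table <- do.call(rbind, lapply(names(pins), function(pn) {
    data.frame(pin = pn, endpoint = c("top", "bottom"),
               rbind(pins[[pn]]$top_components_mm,
                     pins[[pn]]$bottom_components_mm))
  }))
  names(component_table)[3:5] <- c("x_mm", "y_mm", "z_mm")
  rownames(component_table) <- NULL

  structure(list(icp = fit, quality = quality, pins = pins,
                 scale_factors = scale_factors,
                 summary_table = summary_table,
                 component_table = component_table,
                 case_id = case_id),
            class = "pin_migration")
}

#' @export
print.pin_migration <- function(x, digits = 2, ...) {
  cat(sprintf("Pin migration report — %s\n", x$case_id))
  cat(sprintf("  femur registration: %d iterations, final E %.4g mm^2\n",
              x$icp$iterations_run, x$icp$cost_trace[x$icp$iterations_run]))
  cat(sprintf("  quality: mean %.2f mm, max %.2f mm, <0.5 mm %.2f%%, <2 mm %.2f%%\n",
              x$quality$mean_distance_mm, x$quality$max_distance_mm,
              100 * x$quality$fractions[1], 100 * x$quality$fractions[2]))
  cat("\nRelative angle and endpoint movement:\n")
  s <- x$summary_table
  s[-1] <- lapply(s[-1], round, digits = digits)
  print(s, row.names = FALSE)
  cat("\nDisplacement components in the postoperative pin frame (mm):\n")
  comp <- x$component_table
  comp[-(1:2)] <- lapply(comp[-(1:2)], round, digits = digits)
  print(comp, row.names = FALSE)
  invisible(x)
}

#' @export
summary.pin_migration <- function(object, ...) object

#' @export
plot.pin_migration <- function(x, ...) {
  s <- x$summary_table
  vals <- rbind(s$top_movement_mm, s$bottom_movement_mm)
  graphics::barplot(vals, beside = TRUE, names.arg = s$pin,
                    legend.text = c("top", "bottom"),
                    ylab = "endpoint movement (mm)",
                    main = paste("Pin migration —", x$case_id), ...)
  invisible(x)
}

# ---------------------------------------------------------------------------
# Command-style pipeline entry points (wrapped by the pinmigrate CLI script).
# Validation problems raise condition class "pinmigrate_validation_error",
# numerical ones "pinmigrate_numerical_error"; the CLI maps these to exit
# codes 2 and 3.

#' Simulate phantom cases to disk
#'
#' Writes, per case, the six cloud files (PLY ascii), a ready-to-use
#' `case.yaml` bundle, and the ground truth as `truth.json`.
#'
#' @param outdir output directory.
#' @param cases number of cases.
#' @param seed master seed.
#' @param noise_sd_mm,outlier_fraction generator settings.
#' @return character vector of case directories, invisibly.
#' @export
cmd_simulate <- function(outdir, cases = 1L, seed = 1L, noise_sd_mm = 0.3,
                         outlier_fraction = 0.05) {
  suite <- regression_suite(cases, seed = seed, noise_sd_mm = noise_sd_mm,
                            outlier_fraction = outlier_fraction)
  dirs <- character(0)
  for (i in seq_along(suite)) {
    ph <- suite[[i]]
    cdir <- file.path(outdir, sprintf("case-%02d", i))
    dir.create(cdir, showWarnings = FALSE, recursive = TRUE)
    files <- list()
    for (ep in c("postop", "followup"))
      for (role in names(ph[[ep]])) {
        f <- sprintf("%s_%s.ply", ep, role)
        write_point_cloud(ph[[ep]][[role]], file.path(cdir, f))
        files[[ep]][[role]] <- f
      }
    yaml::write_yaml(list(
      case_id = sprintf("case-%02d", i),
      postop = files$postop, followup = files$followup,
      proximal = list(length_mm = ph$spec$pins$proximal$length_mm,
                      hook_hint = as.numeric(ph$truth$pins$proximal$hook_direction)),
      distal = list(length_mm = ph$spec$pins$distal$length_mm,
                    hook_hint = as.numeric(ph$truth$pins$distal$hook_direction))),
      file.path(cdir, "case.yaml"))
    jsonlite::write_json(phantom_truth_list(ph), file.path(cdir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    dirs <- c(dirs, cdir)
  }
  invisible(dirs)
}

phantom_truth_list <- function(ph) {
  list(seed = ph$spec$seed,
       global_transform = list(
         rotation = ph$truth$global_transform$rotation,
         translation = ph$truth$global_transform$translation),
       pins = lapply(ph$truth$pins, function(p)
         list(axial_mm = p$axial_mm, tilt_deg = p$tilt_deg,
              relative_angle_deg = p$relative_angle_deg,
              top_displacement_mm = p$top_displacement_mm,
              bottom_displacement_mm = p$bottom_displacement_mm,
              top_components_mm = as.list(p$top_components_mm),
              bottom_components_mm = as.list(p$bottom_components_mm))))
}

validation_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("pinmigrate_validation_error",
                                             "error", "condition")))
}

load_bundle <- function(case) {
  if (inherits(case, "case_bundle")) return(case)
  if (!is.character(case) || !file.exists(case))
    validation_error("case bundle not found: ", case)
  read_case_bundle(case)
}

#' Register the femur reference of a case
#'
#' Runs [icp()] on the two partial-femur clouds and writes the fitted
#' transform (`transform.json`), the quality metrics (`quality.json`), and
#' the registered follow-up femur cloud (`registered_femur.ply`).
#'
#' @param case path to a case YAML, or a `"case_bundle"`.
#' @param out output directory.
#' @param control an [icp_control()].
#' @param thresholds quality thresholds in mm.
#' @return list with `fit` and `quality`, invisibly.
#' @export
cmd_register <- function(case, out, control = icp_control(),
                         thresholds = c(0.5, 2)) {
  bundle <- load_bundle(case)
  fit <- icp(bundle$followup$femur_ref, bundle$postop$femur_ref,
             control = control)
  q <- registration_quality(fitted(fit), bundle$postop$femur_ref,
                            thresholds = thresholds)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(list(
    case_id = bundle$case_id,
    rotation = fit$transform$rotation,
    translation = fit$transform$translation,
    initial_translation = fit$initial_translation,
    iterations = fit$iterations_run, converged = fit$converged,
    cost_trace_mm2 = fit$cost_trace),
    file.path(out, "transform.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  jsonlite::write_json(quality_to_list(q), file.path(out, "quality.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_point_cloud(fitted(fit), file.path(out, "registered_femur.ply"))
  invisible(list(fit = fit, quality = q))
}

#' Measure pin migration for a case and write the report
#'
#' Runs the full [pin_migration()] pipeline and writes the JSON/CSV report,
#' the transformed follow-up pin clouds, and a displacement-vector cloud
#' (points sampled along the top/bottom endpoint travel segments, for
#' visual inspection in any PLY viewer).
#'
#' @inheritParams cmd_register
#' @param ... passed to [pin_migration()].
#' @return the `"pin_migration"` report, invisibly.
#' @export
cmd_measure <- function(case, out, control = icp_control(), ...) {
  bundle <- load_bundle(case)
  report <- pin_migration(bundle, control = control, ...)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write_report(report, out)
  seg <- list()
  for (pn in names(report$pins)) {
    p <- report$pins[[pn]]
    write_point_cloud(p$after$cloud,
                      file.path(out, sprintf("registered_%s_pin.ply", pn)))
    tt <- seq(0, 1, length.out = 50)
    seg[[pn]] <- rbind(
      outer(1 - tt, p$before$top) + outer(tt, p$after$top),
      outer(1 - tt, p$before$bottom) + outer(tt, p$after$bottom))
  }
  write_point_cloud(do.call(rbind, seg),
                    file.path(out, "displacement_vectors.ply"))
  invisible(report)
}

#' Evaluate registration quality for a case
#'
#' Reuses `transform.json` in `out` when present (from [cmd_register()]),
#' otherwise registers first; writes `quality.json`.
#'
#' @inheritParams cmd_register
#' @return the `"registration_quality"`, invisibly.
#' @export
cmd_evaluate <- function(case, out, control = icp_control(),
                         thresholds = c(0.5, 2)) {
  bundle <- load_bundle(case)
  tf_path <- file.path(out, "transform.json")
  if (file.exists(tf_path)) {
    tf <- jsonlite::read_json(tf_path, simplifyVector = TRUE)
    transform <- rigid_transform(tf$rotation, tf$translation, tol = 1e-6)
    moved <- apply_transform(bundle$followup$femur_ref, transform)
  } else {
    fit <- icp(bundle$followup$femur_ref, bundle$postop$femur_ref,
               control = control)
    moved <- fitted(fit)
  }
  q <- registration_quality(moved, bundle$postop$femur_ref,
                            thresholds = thresholds)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(quality_to_list(q), file.path(out, "quality.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(q)
}

#' Traditional landmark-method comparison
#'
#' Reads an endpoint coordinate CSV (see [read_endpoints()]) and, when a
#' manual reference CSV (`label,manual_mm`) is given, produces the
#' displacement / relative-error comparison table; writes it as CSV and
#' JSON.
#'
#' @param endpoints_csv endpoint coordinate table.
#' @param out output directory.
#' @param manual_csv optional reference measurement table.
#' @return the comparison data.frame, invisibly.
#' @export
cmd_traditional <- function(endpoints_csv, out, manual_csv = NULL) {
  if (!file.exists(endpoints_csv))
    validation_error("endpoint CSV not found: ", endpoints_csv)
  ep <- read_endpoints(endpoints_csv)
  manual <- NULL
  if (!is.null(manual_csv)) {
    mdf <- read.csv(manual_csv, stringsAsFactors = FALSE)
    manual <- stats::setNames(mdf$manual_mm, mdf$label)
  }
  cmp <- traditional_comparison(ep, manual)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write.csv(cmp, file.path(out, "traditional_comparison.csv"),
            row.names = FALSE)
  jsonlite::write_json(cmp, file.path(out, "traditional_comparison.json"),
                       digits = NA, pretty = TRUE)
  invisible(cmp)
}
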