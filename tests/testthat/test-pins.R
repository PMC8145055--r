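test_that("PCA recovers the axis of a cylinder, also after rotation", {
  set.seed(17)
  cyl <- cylinder_cloud(20000, 90, 3.25)
  ax <- fit_pin_axis(cyl)
  expect_lt(relative_angle(ax$axis, c(0, 0, 1)), 0.1)

  R <- rotation_about_axis(c(1, -2, 0.5), 25)
  rot <- apply_transform(cyl, rigid_transform(R))
  ax2 <- fit_pin_axis(rot, top_hint = as.vector(R %*% c(0, 0, 1)))
  expect_lt(relative_angle(ax2$axis, as.vector(R %*% c(0, 0, 1))), 1)

  noisy <- cylinder_cloud(20000, 90, 3.25, noise_sd = 0.3)
  expect_lt(relative_angle(fit_pin_axis(noisy)$axis, c(0, 0, 1)), 1)

  two <- point_cloud(rbind(c(0, 0, 0), c(1, 2, 2)))
  expect_equal(fit_pin_axis(two, top_hint = c(1, 2, 2))$axis, c(1, 2, 2) / 3,
               tolerance = 1e-12)

  iso <- point_cloud(rbind(diag(3), -diag(3)))
  expect_error(fit_pin_axis(iso), "ambiguous")
})

test_that("endpoints and extent match the cylinder's closed form", {
  set.seed(18)
  z <- runif(4000, 0, 90); th <- runif(4000, 0, 2 * pi)
  cyl <- point_cloud(cbind(cos(th), sin(th), z))
  ends <- compute_obb_endpoints(cyl, c(0, 0, 1))
  expect_equal(ends$extent_mm, max(z) - min(z), tolerance = 1e-12)
  expect_equal(unname(ends$top), c(0, 0, 90), tolerance = 0.5)
  expect_equal(unname(ends$bottom), c(0, 0, 0), tolerance = 0.5)

  slab <- point_cloud(cbind(runif(50), runif(50), 0))
  e2 <- compute_obb_endpoints(slab, c(0, 0, 1))
  expect_lt(e2$extent_mm, 1e-9)
  expect_equal(e2$top, e2$bottom, tolerance = 1e-6)
})

test_that("phantom pin extent matches its 80 mm nominal length", {
  ph <- generate_phantom(phantom_spec(seed = 19, noise_sd_mm = 0))
  pm <- pin_model(ph$postop$proximal_pin, nominal_length_mm = 80)
  expect_lt(abs(pm$extent_mm - 80), 1)
  expect_equal(euclidean_distance(pm$top, pm$bottom), pm$measured_length_mm,
               tolerance = 1e-6)
})

test_that("scale calibration recovers physical units", {
  expect_equal(calibrate_scale(80, 80), 1)
  expect_equal(calibrate_scale(40, 80), 2)
  expect_error(calibrate_scale(-1, 80), "positive")
  expect_error(calibrate_scale(80, 0), "positive")

  ph <- generate_phantom(phantom_spec(seed = 20, noise_sd_mm = 0))
  half <- point_cloud(unclass(ph$postop$distal_pin) * 0.5)
  pm <- pin_model(half, nominal_length_mm = 90)
  f <- pm$scale_factor
  rescaled <- pin_model(point_cloud(unclass(half) * f),
                        nominal_length_mm = 90)
  expect_lt(abs(rescaled$extent_mm - 90), 0.5)
  # calibrating a calibrated cloud is a no-op
  expect_lt(abs(rescaled$scale_factor * f - f), 1e-9 * f)
})

test_that("relative angle is sign-invariant and matches closed forms", {
  v <- c(0.6, 0.8, 0) / 1
  expect_equal(relative_angle(v, v), 0)
  expect_equal(relative_angle(v, -v), 0)
  expect_equal(relative_angle(c(1, 0, 0), c(1, 1, 0) / sqrt(2)), 45,
               tolerance = 1e-9)
  expect_error(relative_angle(c(1, 1, 0), c(1, 0, 0)), "unit")
})

test_that("pin frames are orthonormal, right-handed, and follow the hook", {
  f1 <- build_pin_frame(list(axis = c(0, 0, 1), hook_direction = c(0, 1, 0),
                             center = c(0, 0, 0)))
  expect_equal(f1$y_axis, c(0, 1, 0), tolerance = 1e-12)
  expect_equal(f1$x_axis, c(1, 0, 0), tolerance = 1e-12)

  f2 <- build_pin_frame(list(axis = c(0, 0, 1),
                             hook_direction = c(0, 1, 1) / sqrt(2),
                             center = c(0, 0, 0)))
  expect_equal(f2$y_axis, c(0, 1, 0), tolerance = 1e-12)
  expect_equal(f2$x_axis, c(1, 0, 0), tolerance = 1e-12)

  set.seed(21)
  for (i in 1:20) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    hk <- rnorm(3)
    fr <- tryCatch(build_pin_frame(list(axis = ax, hook_direction = hk,
                                        center = rnorm(3))),
                   error = function(e) NULL)
    if (is.null(fr)) next  # hook happened to be near-parallel
    M <- rbind(fr$x_axis, fr$y_axis, fr$z_axis)
    expect_lt(max(abs(M %*% t(M) - diag(3))), 1e-9)
    xyz <- c(fr$y_axis[2] * fr$z_axis[3] - fr$y_axis[3] * fr$z_axis[2],
             fr$y_axis[3] * fr$z_axis[1] - fr$y_axis[1] * fr$z_axis[3],
             fr$y_axis[1] * fr$z_axis[2] - fr$y_axis[2] * fr$z_axis[1])
    expect_equal(fr$x_axis, xyz, tolerance = 1e-9)
  }

  expect_error(build_pin_frame(list(axis = c(0, 0, 1),
                                    hook_direction = c(0, 1e-4, 1),
                                    center = c(0, 0, 0))),
               "degenerate")
})

test_that("displacement decomposition preserves the norm and matches the matrix oracle", {
  ident <- build_pin_frame(list(axis = c(0, 0, 1), hook_direction = c(0, 1, 0),
                                center = c(0, 0, 0)))
  v <- c(2.07, 0.20, -3.39)
  expect_equal(unname(decompose_displacement(v, ident)), v, tolerance = 1e-12)

  set.seed(22)
  for (i in 1:20) {
    fr <- build_pin_frame(list(axis = unitize(rnorm(3)),
                               hook_direction = rnorm(3), center = rnorm(3)))
    vec <- runif(3, -10, 10)
    comp <- decompose_displacement(vec, fr)
    expect_equal(sqrt(sum(comp^2)), sqrt(sum(vec^2)), tolerance = 1e-9)
    M <- rbind(fr$x_axis, fr$y_axis, fr$z_axis)
    expect_equal(unname(comp), as.vector(M %*% vec), tolerance = 1e-12)
  }

  fr90 <- build_pin_frame(list(axis = c(0, 0, 1),
                               hook_direction = c(-1, 0, 0),
                               center = c(0, 0, 0)))
  # y axis now -x, x axis now -y: (1,0,0) decomposes to (0,-1,0)
  expect_equal(unname(decompose_displacement(c(1, 0, 0), fr90)), c(0, -1, 0),
               tolerance = 1e-12)
})

test_that("endpoint displacement matches closed forms and the phantom truth", {
  ph <- generate_phantom(phantom_spec(seed = 23, noise_sd_mm = 0))
  a <- pin_model(ph$postop$proximal_pin, 80)
  expect_equal(endpoint_displacement(a, a), list(top_mm = 0, bottom_mm = 0))

  shifted <- point_cloud(sweep(unclass(ph$postop$proximal_pin), 2L,
                               -5 * a$axis))
  b <- pin_model(shifted, 80, top_hint = a$axis, hook_hint = a$hook_direction)
  mv <- endpoint_displacement(a, b)
  expect_equal(mv$top_mm, 5, tolerance = 0.05)
  expect_equal(mv$bottom_mm, 5, tolerance = 0.05)

  flipped <- list(axis = -a$axis, top = a$top, bottom = a$bottom)
  expect_error(endpoint_displacement(a, flipped), "anti-aligned")

  # -3 mm axial + 2 deg tilt, measured against the analytic truth record
  ph7 <- generate_phantom(phantom_spec(
    seed = 7, migrations = list(proximal = list(axial_mm = -3, tilt_deg = 2),
                                distal = list(axial_mm = -3, tilt_deg = 2))))
  tr <- ph7$truth$pins$proximal
  before <- pin_model(ph7$postop$proximal_pin, 80,
                      hook_hint = tr$hook_direction)
  after_cloud <- apply_transform(ph7$truth$noiseless_followup$proximal_pin,
                                 invert_transform(ph7$truth$global_transform))
  after <- pin_model(after_cloud, 80, top_hint = before$axis,
                     hook_hint = before$hook_direction)
  mv7 <- endpoint_displacement(before, after)
  expect_lt(abs(mv7$top_mm - tr$top_displacement_mm), 0.2)
  expect_lt(abs(mv7$bottom_mm - tr$bottom_displacement_mm), 0.2)
})

test_that("endpoint displacement is invariant to a common rigid transform", {
  set.seed(24)
  ph <- generate_phantom(phantom_spec(seed = 24))
  a <- pin_model(ph$postop$proximal_pin, 80)
  b <- pin_model(ph$postop$distal_pin, 90)
  tf <- rigid_transform(random_rotation(), runif(3, -30, 30))
  a2 <- pin_model(apply_transform(a$cloud, tf), 80,
                  top_hint = as.vector(tf$rotation %*% a$axis))
  b2 <- pin_model(apply_transform(b$cloud, tf), 90,
                  top_hint = as.vector(tf$rotation %*% b$axis))
  m1 <- endpoint_displacement(a, b)
  m2 <- endpoint_displacement(a2, b2)
  expect_equal(m1$top_mm, m2$top_mm, tolerance = 1e-6)
  expect_equal(m1$bottom_mm, m2$bottom_mm, tolerance = 1e-6)
})

test_that("a pure axial migration decomposes onto the z axis", {
  d <- -5
  ph <- generate_phantom(phantom_spec(
    seed = 25, migrations = list(proximal = list(axial_mm = d, tilt_deg = 0),
                                 distal = list(axial_mm = d, tilt_deg = 0))))
  rep <- pin_migration(ph$postop, ph$followup,
                       hook_hints = lapply(ph$truth$pins, `[[`,
                                           "hook_direction"))
  for (pn in c("proximal", "distal")) {
    comp <- rep$pins[[pn]]$top_components_mm
    expect_lt(abs(comp[["z"]] - d), 0.5)
    expect_lt(abs(comp[["x"]]), 0.5)
    expect_lt(abs(comp[["y"]]), 0.5)
  }
})

test_that("the estimated hook direction points at the phantom's hook fin", {
  ph <- generate_phantom(phantom_spec(seed = 26, noise_sd_mm = 0))
  pm <- pin_model(ph$postop$proximal_pin, 80)
  tr <- ph$truth$pins$proximal
  ang <- acos(min(1, sum(pm$hook_direction * tr$hook_direction))) * 180 / pi
  expect_lt(ang, 20)  # a rough but sign-correct estimate
  set.seed(260)
  sym <- cylinder_cloud(5000, 80, 3.25, solid = TRUE)
  ax <- fit_pin_axis(sym)
  expect_error(estimate_hook_direction(sym, ax$axis, ax$center), "symmetric")
})
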