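test_that("center_align returns the centroid-matching translation", {
  set.seed(2)
  Q <- point_cloud(matrix(runif(90, -10, 10), ncol = 3))
  expect_equal(center_align(Q, Q), c(x = 0, y = 0, z = 0))
  P <- point_cloud(sweep(unclass(Q), 2L, -c(5, -3, 2)))
  expect_equal(center_align(P, Q), c(x = -5, y = 3, z = -2), tolerance = 1e-12)
  shifted <- sweep(unclass(P), 2L, -center_align(P, Q))
  expect_lt(sqrt(sum((colMeans(shifted) - colMeans(unclass(Q)))^2)), 1e-9)
})

test_that("nearest-neighbour search agrees with the exhaustive oracle", {
  set.seed(3)
  Q <- point_cloud(matrix(runif(900, -10, 10), ncol = 3))
  P <- point_cloud(matrix(runif(450, -10, 10), ncol = 3))
  fast <- nearest_neighbours(Q, P)
  slow <- brute_nn(Q, P)
  expect_identical(fast$index, slow$index)
  expect_equal(fast$distance, slow$distance, tolerance = 1e-12)
})

test_that("correspondences on identical clouds are exact self-matches", {
  set.seed(4)
  Q <- point_cloud(matrix(runif(600, -10, 10), ncol = 3))
  cs <- find_correspondences(Q, Q, icp_control(direction_k = 5))
  expect_identical(cs$pairs$ip, cs$pairs$iq)
  expect_equal(max(cs$pairs$distance), 0)
  expect_identical(cs$n_rejected, 0L)
})

test_that("a 1 mm normal shift of a sheet yields distances <= 1 mm", {
  g <- as.matrix(expand.grid(x = seq(0, 10, 0.5), y = seq(0, 10, 0.5)))
  Q <- point_cloud(cbind(g, 0))
  P <- point_cloud(cbind(g, 1))
  cs <- find_correspondences(P, Q, icp_control(use_rejection = FALSE))
  expect_true(all(cs$pairs$distance <= 1 + 1e-12))
  slow <- brute_nn(Q, P)
  expect_equal(cs$pairs$distance, slow$distance, tolerance = 1e-12)
})

test_that("opposed direction vectors reject every pair at a 60 degree threshold", {
  g <- as.matrix(expand.grid(x = seq(0, 10, 1), y = seq(0, 10, 1)))
  P <- point_cloud(cbind(g, 0.1))
  Q <- point_cloud(cbind(g, 0))
  up <- matrix(rep(c(0, 0, 1), each = nrow(g)), ncol = 3)
  cs <- find_correspondences(P, Q, icp_control(rejection_angle_deg = 60),
                             directions_P = up, directions_Q = -up)
  expect_identical(cs$n_accepted, 0L)
  expect_identical(cs$n_rejected, nrow(g))
})

test_that("the rigid update recovers a known rotation to 1e-9", {
  set.seed(5)
  P <- point_cloud(matrix(runif(150, -10, 10), ncol = 3))
  R <- rotation_about_axis(c(1, 1, 1) / sqrt(3), 30)
  truth <- rigid_transform(R, c(2, -7, 4))
  Q <- apply_transform(P, truth)
  pairs <- data.frame(ip = seq_len(nrow(P)), iq = seq_len(nrow(P)))
  est <- estimate_rigid_update(pairs, P, Q)
  expect_lt(max(abs(est$rotation - truth$rotation)), 1e-9)
  expect_lt(max(abs(est$translation - truth$translation)), 1e-9)

  ident <- estimate_rigid_update(pairs, P, P)
  expect_lt(max(abs(ident$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(ident$translation)), 1e-9)
})

test_that("the rigid update never returns a reflection for mirrored near-planar data", {
  set.seed(6)
  m <- cbind(runif(60, -10, 10), runif(60, -10, 10), rnorm(60, 0, 0.01))
  P <- point_cloud(m)
  Q <- point_cloud(m %*% diag(c(1, 1, -1)))  # mirrored target
  pairs <- data.frame(ip = 1:60, iq = 1:60)
  est <- estimate_rigid_update(pairs, P, Q)
  expect_equal(det(est$rotation), 1, tolerance = 1e-9)
  # brute-force check over the two det corrections: +1 branch must be optimal
  # among proper rotations, i.e. the returned cost is <= cost of any tested
  # proper rotation
  cost <- function(tf) mean(rowSums((unclass(apply_transform(P, tf)) -
                                     unclass(Q))^2))
  base <- cost(est)
  for (i in 1:20) {
    cand <- rigid_transform(random_rotation(), runif(3, -2, 2))
    expect_lte(base, cost(cand) + 1e-9)
  }
})

test_that("degenerate correspondence geometry raises an error", {
  line <- point_cloud(cbind(seq(0, 10, 1), 0, 0))
  pairs <- data.frame(ip = 1:11, iq = 1:11)
  expect_error(estimate_rigid_update(pairs, line, line), "collinear")
  two <- point_cloud(rbind(c(0, 0, 0), c(1, 1, 1)))
  expect_error(estimate_rigid_update(data.frame(ip = 1:2, iq = 1:2), two, two),
               "at least 3")
})

test_that("ICP on identical clouds converges immediately to the identity", {
  set.seed(8)
  Q <- generate_phantom(phantom_spec(seed = 8, n_femur_points = 500,
                                     noise_sd_mm = 0,
                                     outlier_fraction = 0))$postop$femur_ref
  fit <- icp(Q, Q)
  expect_lte(fit$iterations_run, 2L)
  expect_true(fit$converged)
  expect_lt(fit$cost_trace[fit$iterations_run], 1e-12)
  expect_lt(rotation_angle_deg(fit$transform$rotation), 1e-7)
  expect_lt(max(abs(fit$transform$translation)), 1e-7)
})

test_that("ICP recovers a known offset of the noiseless phantom reference", {
  G <- rigid_transform(rotation_about_axis(c(0, 0, 1), 10), c(5, -3, 2))
  ph <- generate_phantom(phantom_spec(seed = 42, noise_sd_mm = 0,
                                      outlier_fraction = 0,
                                      global_transform = G,
                                      migrations = zero_migration))
  fit <- icp(ph$followup$femur_ref, ph$postop$femur_ref)
  d <- transform_discrepancy(fit$transform, invert_transform(G),
                             at = ph$followup$femur_ref)
  expect_lt(d$angle_deg, 0.1)
  expect_lt(d$translation_mm, 0.1)
})

test_that("ICP tolerates 0.3 mm noise on the phantom", {
  ph <- generate_phantom(phantom_spec(seed = 42, outlier_fraction = 0))
  fit <- icp(ph$followup$femur_ref, ph$postop$femur_ref)
  d <- transform_discrepancy(fit$transform,
                             invert_transform(ph$truth$global_transform),
                             at = ph$followup$femur_ref)
  expect_lt(d$angle_deg, 1)
  expect_lt(d$translation_mm, 0.5)
})

test_that("the accumulated transform stays rigid and the fit is frame-invariant", {
  ph <- generate_phantom(phantom_spec(seed = 23, n_femur_points = 800))
  P <- ph$followup$femur_ref; Q <- ph$postop$femur_ref
  fit <- icp(P, Q)
  R <- fit$transform$rotation
  expect_lt(max(abs(crossprod(R) - diag(3))), 1e-9)
  expect_equal(det(R), 1, tolerance = 1e-9)

  C <- rigid_transform(rotation_about_axis(c(1, 0, 1), 30), c(100, -50, 20))
  fit2 <- icp(apply_transform(P, C), apply_transform(Q, C))
  a <- predict(fit, P)
  b <- apply_transform(predict(fit2, apply_transform(P, C)),
                       invert_transform(C))
  expect_lt(max(abs(unclass(a) - unclass(b))), 1e-6)
})

test_that("exact-copy inputs converge to machine-level cost from a 20 deg / 20 mm offset", {
  G <- rigid_transform(rotation_about_axis(c(1, 2, 3), 20), c(20, -20, 10))
  ph <- generate_phantom(phantom_spec(seed = 9, noise_sd_mm = 0,
                                      outlier_fraction = 0,
                                      global_transform = G,
                                      migrations = zero_migration))
  fit <- icp(ph$followup$femur_ref, ph$postop$femur_ref)
  expect_lt(fit$cost_trace[fit$iterations_run], 1e-10)
})

test_that("cost trace is non-increasing with rejection disabled", {
  for (s in 1:5) {
    ph <- generate_phantom(phantom_spec(seed = 100 + s, n_femur_points = 800,
                                        outlier_fraction = 0))
    fit <- icp(ph$followup$femur_ref, ph$postop$femur_ref,
               icp_control(use_rejection = FALSE, cost_tolerance = 0,
                           max_iterations = 40))
    expect_true(all(diff(fit$cost_trace) <= 1e-9))
  }
})

test_that("rejection makes ICP robust to appended outliers", {
  base <- phantom_spec(seed = 31, outlier_fraction = 0)
  with_out <- phantom_spec(seed = 31, outlier_fraction = 0.1)
  ph0 <- generate_phantom(base)
  ph1 <- generate_phantom(with_out)
  f0 <- icp(ph0$followup$femur_ref, ph0$postop$femur_ref)
  f1 <- icp(ph1$followup$femur_ref, ph1$postop$femur_ref)
  d <- transform_discrepancy(f1$transform, f0$transform,
                             at = ph0$followup$femur_ref)
  expect_lt(d$angle_deg, 0.5)
  expect_lt(d$translation_mm, 0.5)
})

test_that("icp object methods behave like a fitted model", {
  ph <- generate_phantom(phantom_spec(seed = 13, n_femur_points = 500))
  fit <- icp(ph$followup$femur_ref, ph$postop$femur_ref)
  expect_s3_class(fit, "icp")
  expect_identical(dim(coef(fit)), c(3L, 4L))
  expect_identical(length(fit$cost_trace), fit$iterations_run)
  expect_equal(unclass(predict(fit, ph$followup$femur_ref)),
               unclass(fitted(fit)), ignore_attr = TRUE)
  r <- residuals(fit)
  expect_length(r, nrow(ph$followup$femur_ref))
  expect_true(all(r >= 0))
  expect_output(print(fit), "ICP rigid registration")
  expect_output(print(summary(fit)), "quality")
})
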