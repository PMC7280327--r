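# Length sweeps, quartic fitting, tendon-excursion moment arms, fan
# summaries and range agreement.

make_const_ma <- function(values_m, theta = seq(-10, 60, 2)) {
  structure(list(coordinate = "flexion", theta_deg = theta,
                 r = matrix(rep(values_m, each = length(theta)),
                            nrow = length(values_m), byrow = TRUE),
                 sign = -1),
            class = "momentarm_curve")
}

test_that("sweep grids have the documented size and limits", {
  hx <- make_hinge_fixture()
  curve <- sweep_lengths(hx$fibers, hx$skeleton, "flexion", c(-10, 60), 2)
  expect_length(curve$theta_deg, 36L)
  expect_equal(range(curve$theta_deg), c(-10, 60))
  expect_error(sweep_lengths(hx$fibers, hx$skeleton, "flexion", c(10, -10), 2),
               "hi > lo")
  expect_error(sweep_lengths(hx$fibers, hx$skeleton, "flexion", c(-10, 60), 0),
               "step")
})

test_that("hinge length sweep matches the law of cosines", {
  toy <- hinge_toy(0.08, 0.11, 100)
  hx <- make_hinge_fixture(toy)
  curve <- sweep_lengths(hx$fibers, hx$skeleton, "flexion", c(-10, 60), 2)
  oracle <- hinge_oracle(toy, curve$theta_deg)
  expect_lt(max(abs(curve$lengths[1L, ] - oracle$length)), 1e-9)
})

test_that("a fibre fixed to the parent keeps constant length", {
  skel <- make_two_bone_skeleton()
  pts <- array(0, dim = c(1L, 3L, 3L))
  pts[1L, , ] <- rbind(c(0, 0, 0), c(0.01, 0, 0.05), c(0, 0, 0.1))
  fib <- fiber_set(pts)
  fib$bindings <- list(
    bones = array("parent_bone", dim = c(1L, 3L, 2L)),
    w = array(rep(c(1, 0), each = 3L), dim = c(1L, 3L, 2L)), a = 0)
  curve <- sweep_lengths(fib, skel, "flexion", c(-10, 60), 2)
  expect_lt(diff(range(curve$lengths)), 1e-15)
  ma <- excursion_moment_arms(fit_quartic(curve))
  expect_lt(max(abs(ma$r)), 1e-12)
})

test_that("quartic fitting is exact on representable curves", {
  theta <- seq(-10, 60, 2)
  x <- muscledecomp:::deg2rad(theta)
  xc <- x - mean(x)
  quartic <- 0.2 + 0.05 * xc - 0.01 * xc^2 + 0.004 * xc^3 + 0.002 * xc^4
  curve <- structure(list(coordinate = "flexion", theta_deg = theta,
                          lengths = rbind(quartic), fit = NULL),
                     class = "length_curve")
  fitted <- fit_quartic(curve)
  expect_equal(as.vector(fitted$fit$coef),
               c(0.2, 0.05, -0.01, 0.004, 0.002), tolerance = 1e-9)
  # constant curve: all non-constant coefficients vanish
  const <- curve
  const$lengths <- rbind(rep(0.15, length(theta)))
  cf <- fit_quartic(const)$fit$coef
  expect_lt(max(abs(cf[2:5])), 1e-12)
  # smooth trigonometric curve: small residual over the working range
  cosc <- curve
  cosc$lengths <- rbind(2 * cos(x / 2))
  expect_lt(fit_quartic(cosc)$fit$residual, 1e-5)
  short <- curve
  short$theta_deg <- theta[1:4]
  short$lengths <- curve$lengths[, 1:4, drop = FALSE]
  expect_error(fit_quartic(short), ">= 5")
})

test_that("excursion moment arms match the hinge closed form", {
  toy <- hinge_toy(0.1, 0.1, 90)
  hx <- make_hinge_fixture(toy)
  curve <- fit_quartic(sweep_lengths(hx$fibers, hx$skeleton, "flexion",
                                     c(-10, 60), 2))
  ma <- excursion_moment_arms(curve)
  # at theta = 0 the included angle is 90 degrees: |r| = ab sin / l
  at0 <- which(curve$theta_deg == 0)
  expect_equal(abs(ma$r[1L, at0]), 0.1 * 0.1 * sin(pi / 2) / (0.1 * sqrt(2)),
               tolerance = 1e-3)
  # agreement with central differences of the raw samples where smooth
  fd <- (curve$lengths[1L, 3:36] - curve$lengths[1L, 1:34]) /
    (2 * muscledecomp:::deg2rad(2))
  expect_lt(max(abs(-fd - ma$r[1L, 2:35]) / abs(fd)), 0.02)
  # sign flag flips the curve
  ma_pos <- excursion_moment_arms(curve, sign = 1)
  expect_equal(ma_pos$r, -ma$r)
  expect_error(excursion_moment_arms(curve, sign = 2), "sign")
})

test_that("excursion and geometric methods agree in sign and magnitude", {
  toy <- hinge_toy(0.1, 0.1, 90)
  hx <- make_hinge_fixture(toy)
  curve <- fit_quartic(sweep_lengths(hx$path, hx$skeleton, "flexion",
                                     c(-10, 10), 2))
  ma <- excursion_moment_arms(curve)
  geo <- vapply(curve$theta_deg, function(th) {
    geometric_moment_arm(hx$path, hx$skeleton, joint_pose(flexion = th),
                         hx$axis)
  }, 0)
  expect_lt(max(abs(ma$r[1L, ] - geo)), 1e-6)
  expect_true(all(sign(ma$r[1L, ]) == sign(geo)))
})

test_that("fan summaries report envelopes and population statistics", {
  fan1 <- summarize_fan(make_const_ma(0.02))
  expect_equal(fan1$min_cm, 2)
  expect_equal(fan1$max_cm, 2)
  expect_equal(fan1$mean_cm, 2)
  expect_equal(fan1$sd_cm, 0)

  fan2 <- summarize_fan(make_const_ma(c(0.01, 0.03)))
  expect_equal(c(fan2$min_cm, fan2$max_cm, fan2$mean_cm), c(1, 3, 2))

  vals <- seq(0.01, 0.05, length.out = 100L)
  fan3 <- summarize_fan(make_const_ma(vals))
  sd_closed <- sqrt(mean((vals * 100 - mean(vals * 100))^2))
  expect_equal(fan3$sd_cm, sd_closed, tolerance = 1e-9)
  expect_true(fan3$min_cm <= fan3$mean_cm && fan3$mean_cm <= fan3$max_cm)
})

test_that("range agreement counts inclusive envelope membership", {
  ma <- make_const_ma(c(0.01, 0.03))
  npose <- length(ma$theta_deg)
  expect_equal(range_agreement(ma, rep(0.02, npose)), 100L)
  expect_equal(range_agreement(ma, rep(0.08, npose)), 0L)
  half <- rep(c(0.02, 0.08), length.out = npose)
  expect_equal(range_agreement(ma, half), 50L)
  # boundary values are inside (closed interval)
  expect_equal(range_agreement(ma, rep(0.03, npose)), 100L)
  expect_error(range_agreement(ma, rep(0.02, npose - 1L)), "poses")
  # invariant to fibre order and to fibres inside the envelope
  ma_rev <- ma; ma_rev$r <- ma$r[2:1, ]
  ma_add <- ma; ma_add$r <- rbind(ma$r, rep(0.02, npose))
  ref <- rep(c(0.02, 0.05), length.out = npose)
  expect_equal(range_agreement(ma, ref), range_agreement(ma_rev, ref))
  expect_equal(range_agreement(ma, ref), range_agreement(ma_add, ref))
})

test_that("moment-arm CSV export has the documented columns", {
  ma <- make_const_ma(c(0.01, 0.02), theta = seq(0, 10, 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_momentarm_csv(ma, path)
  df <- utils::read.csv(path)
  expect_named(df, c("coordinate", "pose_deg", "fiber_id", "moment_arm_cm"))
  expect_equal(nrow(df), 2L * 6L)
  expect_equal(sort(unique(df$moment_arm_cm)), c(1, 2))
})
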