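test_that("body frame from an axis-aligned stand-stoop gesture is the identity", {
  bf <- create_body_fixed_frame(diag(3), rot_y(30 * pi / 180))
  expect_equal(unclass(bf), diag(3), tolerance = 1e-12)
})

test_that("body frame recovers the heading under arbitrary mounting", {
  for (seed in 1:4) {
    m <- random_rot(seed)
    heading <- 45 * pi / 180
    stand <- rot_z(heading) %*% m
    stoop <- rot_z(heading) %*% rot_y(30 * pi / 180) %*% m
    bf <- create_body_fixed_frame(stand, stoop)
    # oracle: the gesture rotation's unit-eigenvalue eigenvector, via eigen()
    q <- stoop %*% t(stand)
    ev <- eigen(q)
    axis <- Re(ev$vectors[, which.min(abs(Re(ev$values) - 1))])
    axis <- axis / sqrt(sum(axis^2))
    expect_equal(abs(sum(bf[, 2] * axis)), 1, tolerance = 1e-9)
    expect_equal(atan2(bf[2, 1], bf[1, 1]), heading, tolerance = 1e-9)
    expect_equal(bf[3, 1], 0)                 # forward axis horizontal
    expect_equal(bf[, 3], c(0, 0, 1))         # vertical axis exact
    expect_true(is_rotation_matrix(unclass(bf)))
  }
})

test_that("degenerate calibration gestures are rejected", {
  r <- rot_z(0.4)
  expect_error(create_body_fixed_frame(r, r), "degenerate calibration gesture")
  expect_error(create_body_fixed_frame(r, r %*% rot_y(0.05)),
               "degenerate calibration gesture")
  # gesture about the vertical axis has no horizontal component
  expect_error(create_body_fixed_frame(diag(3), rot_z(0.8)),
               "not horizontal")
})

test_that("alignment rotation maps the stand pose onto the body frame", {
  bf <- body_fixed_frame(c(0, 1, 0))
  expect_equal(compute_alignment(unclass(bf), bf), diag(3), tolerance = 1e-12)
  expect_equal(compute_alignment(rot_z(pi / 2), body_fixed_frame(c(0, 1, 0))),
               rot_z(-pi / 2), tolerance = 1e-12)
  for (seed in 1:4) {
    rs <- random_rot(seed)
    bf <- create_body_fixed_frame(diag(3), rot_y(0.5))
    rc <- compute_alignment(rs, bf)
    expect_equal(rs %*% rc, unclass(bf), tolerance = 1e-12)
  }
})

test_that("floating frame follows the waist and reduces to the body frame at rest", {
  bf <- create_body_fixed_frame(diag(3), rot_y(0.5))
  ws <- random_rot(2)
  expect_equal(floating_frame(ws, ws, bf), unclass(bf), tolerance = 1e-12)
  for (delta in c(pi / 2, pi)) {
    expect_equal(floating_frame(rot_z(delta) %*% ws, ws, bf),
                 rot_z(delta) %*% unclass(bf), tolerance = 1e-12)
  }
})

test_that("transformed static samples read gravity regardless of mounting", {
  g <- c(0, 0, 9.80665)
  for (seed in 1:4) {
    r <- random_rot(seed)
    sample <- list(orientation = r, accel = as.vector(t(r) %*% g),
                   gyro = c(0, 0, 0))
    out <- transform_sample(sample, diag(3), t(r))
    expect_equal(out$accel, g, tolerance = 1e-12)
    expect_equal(out$orientation, diag(3), tolerance = 1e-12)
  }
  # identity pipeline leaves the sample untouched
  s0 <- list(orientation = diag(3), accel = c(1, 2, 3), gyro = c(4, 5, 6))
  expect_equal(transform_sample(s0, diag(3), diag(3)), s0)
})

test_that("session calibration recovers the simulated forward direction", {
  s <- quiet_session()
  cal <- calibrate_session(s)
  fwd <- cal$body_frame[, 1]
  expect_lt(acos(min(1, sum(fwd * c(1, 0, 0)))) * 180 / pi, 1)
  for (al in cal$alignment_by_sensor)
    expect_true(is_rotation_matrix(al, tol = 1e-6))
  expect_setequal(names(cal$alignment_by_sensor), names(s$streams))
})

test_that("missing calibration segments or waist stream are errors", {
  s <- quiet_session()
  s_nostoop <- s; s_nostoop$calib$stoop <- NULL
  expect_error(calibrate_session(s_nostoop), "stand/stoop")
  s_nowaist <- s; s_nowaist$streams$waist <- NULL
  expect_error(calibrate_session(s_nowaist), "waist")
})

test_that("transformed feature streams are heading- and mounting-invariant", {
  s <- quiet_session()
  f0 <- session_features(s)
  for (delta in c(pi / 2, pi)) {
    fr <- session_features(rotate_heading(s, delta))
    expect_lt(max(abs(f0$values - fr$values)), 1e-9)
  }
  cfg_id <- sim_config(duration = 10, seed = 3, mounting = "identity",
                       noise_accel = 0, noise_gyro = 0)
  f_id <- session_features(simulate_session(cfg_id))
  expect_lt(max(abs(f0$values - f_id$values)), 1e-9)
  # raw global-frame features are NOT heading-invariant (the problem FBf solves)
  g0 <- session_features(s, frame = "global")
  g90 <- session_features(rotate_heading(s, pi / 2), frame = "global")
  expect_gt(max(abs(g0$values - g90$values)), 1)
})

test_that("every produced rotation satisfies the rotation invariants", {
  s <- quiet_session()
  cal <- calibrate_session(s)
  ts <- transform_session(s, cal)
  idx <- c(1, 500, 1500)
  for (id in names(ts$streams))
    for (i in idx)
      expect_true(is_rotation_matrix(ts$streams[[id]]$orient[, , i], tol = 1e-8))
})
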