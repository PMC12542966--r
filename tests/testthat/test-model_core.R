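# Hill-type musculotendon mechanics, forward kinematics, moment arms and
# tendon slack tuning.

test_that("F_max estimation follows the fibre-stress formula", {
  mat <- material_properties()
  expect_equal(estimate_fmax(0.010, 0.020, mat), 141.5094, tolerance = 1e-6)
  expect_identical(estimate_fmax(0, 0.020, mat), 0)
  # homogeneity: degree 1 in belly mass, degree -1 in fibre length
  expect_equal(estimate_fmax(0.020, 0.020, mat),
               2 * estimate_fmax(0.010, 0.020, mat))
  expect_equal(estimate_fmax(0.010, 0.040, mat),
               estimate_fmax(0.010, 0.020, mat) / 2)
  expect_error(estimate_fmax(0.01, 0), "l0")
  expect_error(estimate_fmax(-0.01, 0.02), "non-negative")
})

test_that("force-length and force-velocity curves have the Hill anchors", {
  expect_identical(active_force_length(1), 1)
  expect_lt(active_force_length(0.7), 1)
  expect_lt(active_force_length(0.7), active_force_length(1))
  # beyond-overlap value pinned from the default curve
  expect_equal(active_force_length(2), 0.007166975, tolerance = 1e-6)
  expect_error(active_force_length(-0.1), "non-negative")

  expect_identical(force_velocity(0), 1)
  expect_equal(force_velocity(-1), 0)
  # mid-range concentric value pinned from the default hyperbola
  expect_equal(force_velocity(-0.5), 1 / 6, tolerance = 1e-12)
  v <- seq(-1, 0, by = 0.05)
  expect_true(all(diff(force_velocity(v)) > 0))       # monotone on shortening
  expect_true(all(force_velocity(seq(0.01, 5, by = 0.1)) <=
                    hill_config()$fv_plateau))        # eccentric plateau
})

test_that("muscle force composes activation, curves and the passive term", {
  act <- toy_hinge_actuator(fmax = 250)
  off <- hill_config(passive = FALSE)
  expect_equal(muscle_force(1, 1, 0, act, off), 250)
  expect_equal(muscle_force(0, 0.9, 0, act, off), 0)
  expect_equal(muscle_force(0.5, 1, 0, act, off), 125)
  expect_error(muscle_force(1.2, 1, 0, act), "activation")
  # passive force: zero at/below l0, positive above, additive
  on <- hill_config(passive = TRUE)
  expect_equal(muscle_force(0, 1, 0, act, on), 0)
  expect_gt(muscle_force(0, 1.2, 0, act, on), 0)
  # monotone non-decreasing in activation at fixed kinematic state
  a <- seq(0, 1, by = 0.1)
  f <- vapply(a, muscle_force, numeric(1), l_norm = 0.95, v_norm = -0.2,
              act = act, config = on)
  expect_true(all(diff(f) >= 0))
})

test_that("forward kinematics reproduces the chain of JCS origins at neutral", {
  m <- toy_model(L1 = 0.1, L2 = 0.08, Lf = 0.05)
  st <- forward_kinematics(m, numeric(0))
  expect_equal(st$thigh$p, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(st$shank$p, c(0, -0.1, 0), tolerance = 1e-12)
  expect_equal(st$foot$p, c(0, -0.18, 0), tolerance = 1e-12)
  # landmark round-trip at neutral: ground position = chain of origins
  expect_equal(landmark_position(m, numeric(0), "foot", "toe"),
               c(0, -0.23, 0), tolerance = 1e-9)
  # JCS triads must be orthonormal to 1e-9
  for (j in m$joints)
    expect_lt(max(abs(crossprod(j$triad) - diag(3))), 1e-9)
})

test_that("musculotendon length: pose independence, law of cosines, collinear via", {
  # two points on the same segment: pose independent
  a0 <- actuator("fixed", list(list(segment = "thigh", point = c(0, 0, 0)),
                               list(segment = "thigh", point = c(0, -0.1, 0))),
                 m_musc = 0.01, l0 = 0.02, fmax = 1)
  m <- toy_model(list(a0))
  for (th in c(0, 0.3, -0.8))
    expect_equal(musculotendon_length(m, c(hip_aa = th), m$actuators$fixed),
                 0.1, tolerance = 1e-12)
  # planar 2-point path across the knee follows the law of cosines
  a <- 0.05; b <- 0.04   # distances of the attachments from the knee centre
  act <- actuator("loc", list(list(segment = "thigh", point = c(0, -0.1 + a, 0)),
                              list(segment = "shank", point = c(0, -b, 0))),
                  m_musc = 0.01, l0 = 0.02, fmax = 1)
  m2 <- toy_model(list(act))
  for (th in c(0.2, 0.7, 1.3)) {
    expected <- sqrt(a^2 + b^2 - 2 * a * b * cos(pi - th))
    expect_equal(musculotendon_length(m2, c(knee_ef = th), m2$actuators$loc),
                 expected, tolerance = 1e-10)
  }
  # a collinear via point leaves the length unchanged
  act3 <- actuator("via", list(list(segment = "thigh", point = c(0, 0, 0)),
                               list(segment = "thigh", point = c(0, -0.05, 0)),
                               list(segment = "thigh", point = c(0, -0.1, 0))),
                   m_musc = 0.01, l0 = 0.02, fmax = 1)
  m3 <- toy_model(list(act3))
  expect_equal(musculotendon_length(m3, c(hip_ef = 0.4), m3$actuators$via),
               0.1, tolerance = 1e-12)
  # unknown segment in the path errors at the model level
  expect_error(msk_model(m$segments, m$joints, list(
    actuator("bad", list(list(segment = "wing", point = c(0, 0, 0)),
                         list(segment = "thigh", point = c(0, -0.1, 0))),
             m_musc = 0.01, l0 = 0.02, fmax = 1)), body_mass = 1),
    "unknown segment")
})

test_that("a cylindrical wrap adds the geodesic detour", {
  # cylinder of radius r centred on the knee axis; a straight path grazing it
  r <- 0.01
  act <- actuator("wrapped",
                  list(list(segment = "thigh", point = c(0, -0.05, 0)),
                       list(segment = "shank", point = c(0, -0.05, 0))),
                  m_musc = 0.01, l0 = 0.02, fmax = 1,
                  wrap = list(segment = "thigh", center = c(0, -0.1, 0),
                              axis = c(1, 0, 0), radius = r,
                              between = c(1, 2)))
  m <- toy_model(list(act))
  # closed form for the symmetric planar wrap: two tangents plus the arc
  # (near extension the straight chord passes within r of the axis)
  th <- 0.2  # knee flexion; attachment rays of length d = 0.05 from centre
  d <- 0.05
  ang <- pi - th                       # angle between the two rays
  tang <- sqrt(d^2 - r^2)
  wrap_angle <- ang - 2 * acos(r / d)
  expect_gt(wrap_angle, 0)
  expected <- 2 * tang + r * wrap_angle
  expect_equal(musculotendon_length(m, c(knee_ef = th), m$actuators$wrapped),
               expected, tolerance = 1e-9)
  # at deep flexion the straight segment clears the cylinder: unchanged
  straight <- sqrt(2 * d^2 - 2 * d^2 * cos(pi - 1.2))
  expect_equal(musculotendon_length(m, c(knee_ef = 1.2), m$actuators$wrapped),
               straight, tolerance = 1e-9)
})

test_that("moment arms match the planar perpendicular-distance oracle", {
  # planar hinge: |moment arm| equals the perpendicular distance from the
  # joint axis to the straight attachment line (analytic geometry oracle)
  a <- 0.05; b <- 0.04
  act <- actuator("planar",
                  list(list(segment = "thigh", point = c(0, -0.1 + a, 0)),
                       list(segment = "shank", point = c(0, -b, 0))),
                  m_musc = 0.01, l0 = 0.02, fmax = 1)
  m <- toy_model(list(act))
  for (th in c(0.3, 0.9, pi / 2)) {
    p1 <- c(-0.1 + a, 0)                       # (y, z) of the thigh point
    p2 <- c(-0.1 - b * cos(th), -b * sin(th))  # shank point after flexion
    k <- c(-0.1, 0)                            # knee centre
    d <- p2 - p1
    dist <- abs(d[1] * (k[2] - p1[2]) - d[2] * (k[1] - p1[1])) / sqrt(sum(d^2))
    arm <- moment_arm(m, c(knee_ef = th), m$actuators$planar, "knee_ef")
    expect_equal(abs(arm), dist, tolerance = 1e-6)
  }
  # an actuator that does not cross the joint has zero arm
  a0 <- actuator("noncross",
                 list(list(segment = "thigh", point = c(0, 0, 0)),
                      list(segment = "thigh", point = c(0, -0.09, 0))),
                 m_musc = 0.01, l0 = 0.02, fmax = 1)
  m0 <- toy_model(list(a0))
  expect_equal(moment_arm(m0, c(knee_ef = 0.5), m0$actuators$noncross,
                          "knee_ef"), 0, tolerance = 1e-12)
  # halving the finite-difference step changes the result by < 1e-8
  a1 <- moment_arm(m, c(knee_ef = 0.9), m$actuators$planar, "knee_ef",
                   h = 1e-4)
  a2 <- moment_arm(m, c(knee_ef = 0.9), m$actuators$planar, "knee_ef",
                   h = 5e-5)
  expect_lt(abs(a1 - a2), 1e-8)
})

test_that("tendon slack tuning follows rigid-tendon algebra", {
  act <- actuator("tune", list(list(segment = "thigh", point = c(0, 0, 0)),
                               list(segment = "thigh", point = c(0, -0.1, 0))),
                  m_musc = 0.01, l0 = 0.02, fmax = 1)
  m <- toy_model(list(act))
  pose <- c(hip_aa = 0)
  expect_equal(tune_tendon_slack(m, m$actuators$tune, pose, 1), 0.08,
               tolerance = 1e-6)
  expect_equal(tune_tendon_slack(m, m$actuators$tune, pose, 0.5), 0.09,
               tolerance = 1e-6)
  expect_error(tune_tendon_slack(m, m$actuators$tune, pose, 10),
               "unreachable")
})
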