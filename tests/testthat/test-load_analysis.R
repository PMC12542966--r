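# Cross-section geometry, beam stresses, joint reaction recursion, safety
# factors and strain conversion.

circle_poly <- function(r, n = 2000, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

ellipse_poly <- function(a, b, n = 2000, rot = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  p <- cbind(a * cos(th), b * sin(th))
  R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2, 2)
  p %*% t(R)
}

test_that("polygon section properties match the closed forms", {
  # solid circle r = 0.01 m
  cs <- section_properties(circle_poly(0.01))
  expect_equal(cs$A, pi * 1e-4, tolerance = 1e-5)
  expect_equal(cs$Iy, pi * 1e-8 / 4, tolerance = 1e-5)
  expect_equal(cs$Iz, pi * 1e-8 / 4, tolerance = 1e-5)
  expect_equal(cs$J, pi * 1e-8 / 2, tolerance = 1e-5)
  expect_equal(cs$Iyz, 0, tolerance = 1e-15)
  expect_equal(cs$y, 0.01, tolerance = 1e-4)
  # ellipse semi-axes 0.010 (y) / 0.005 (z): I about the major axis
  ce <- section_properties(ellipse_poly(0.010, 0.005))
  expect_equal(ce$Iy, pi * 0.010 * 0.005^3 / 4, tolerance = 1e-5)
  expect_equal(ce$Iz, pi * 0.005 * 0.010^3 / 4, tolerance = 1e-5)
  # annulus: outer minus inner closed forms
  ca <- section_properties(circle_poly(0.01), inner = circle_poly(0.006))
  expect_equal(ca$A, pi * (1e-4 - 3.6e-5), tolerance = 1e-5)
  expect_equal(ca$Iy, pi * (0.01^4 - 0.006^4) / 4, tolerance = 1e-5)
  # doubly symmetric sections have zero product of inertia
  expect_equal(ce$Iyz, 0, tolerance = 1e-15)
  # an off-centre polygon is reduced about its own centroid
  cs2 <- section_properties(circle_poly(0.01, center = c(0.3, -0.2)))
  expect_equal(cs2$Iy, cs$Iy, tolerance = 1e-9)
  expect_equal(cs2$centroid, c(0.3, -0.2), tolerance = 1e-9)
  # invariants: J >= max(Iy, Iz); self-intersection rejected
  expect_gte(ca$J, max(ca$Iy, ca$Iz))
  bow <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1)) * 0.01
  expect_error(section_properties(bow), "self-intersect")
})

test_that("pixel-mask and polygon section properties agree within 1%", {
  a <- 0.010; b <- 0.005
  px <- 5e-5   # 0.05 mm resolution
  gy <- seq(-0.012, 0.012, by = px)
  gz <- seq(-0.007, 0.007, by = px)
  mask <- outer(gy, gz, function(y, z) (y / a)^2 + (z / b)^2 <= 1)
  cm <- section_properties(mask, pixel_size = px)
  cp <- section_properties(ellipse_poly(a, b))
  expect_equal(cm$A, cp$A, tolerance = 0.01)
  expect_equal(cm$Iy, cp$Iy, tolerance = 0.01)
  expect_equal(cm$Iz, cp$Iz, tolerance = 0.01)
  expect_equal(cm$y, cp$y, tolerance = 0.01)
})

test_that("beam stresses match hand-evaluated closed forms", {
  cs <- section_properties(circle_poly(0.01, n = 8000))
  # M_y = 1 N m bending a solid circle r = 0.01: sigma = M y / I
  st <- bone_stresses(Fx = 0, Mx = 0, My = 1, Mz = 0, section = cs)
  expect_equal(st$sigma_bend, 1.273240e6, tolerance = 1e-3)
  expect_equal(st$phi_na, 0)
  # axial superposition identities (Eqs. of the stress decomposition)
  st2 <- bone_stresses(Fx = -2e6 * cs$A, Mx = 0, My = 1, Mz = 0, section = cs)
  expect_equal(st2$sigma_ax, -2e6, tolerance = 1e-9)
  expect_equal(st2$sigma_tens, st2$sigma_bend + st2$sigma_ax)
  expect_equal(st2$sigma_comp, -st2$sigma_bend + st2$sigma_ax)
  # torsion: M_x = 2 N m on the solid circle
  st3 <- bone_stresses(Fx = 0, Mx = 2, My = 0, Mz = 0, section = cs)
  expect_equal(st3$sigma_tor, 1.273240e6, tolerance = 1e-3)
  # neutral axis at 45 deg when My = Mz on a symmetric section
  st4 <- bone_stresses(Fx = 0, Mx = 0, My = 1, Mz = 1, section = cs)
  expect_equal(st4$phi_na, pi / 4)
  # homogeneity of degree 1 in the loads (superposition)
  st5 <- bone_stresses(Fx = -10, Mx = 0.5, My = 1.2, Mz = -0.4, section = cs)
  st6 <- bone_stresses(Fx = -30, Mx = 1.5, My = 3.6, Mz = -1.2, section = cs)
  for (cmp in c("sigma_bend", "sigma_ax", "sigma_tor"))
    expect_equal(st6[[cmp]], 3 * st5[[cmp]], tolerance = 1e-12)
  expect_error(bone_stresses(0, 0, 1, 0, list(A = 0, Iy = 1, Iz = 1, J = 1)),
               "geometry")
})

test_that("unsymmetric bending reduces to the per-axis form and is frame invariant", {
  a <- 0.010; b <- 0.005
  cs <- section_properties(ellipse_poly(a, b))
  # with Iyz = 0 the formula reduces to M z / I at the extreme fibre
  My <- 1.3
  expect_equal(asymmetric_bending_stress(My, 0, cs, c(0, b)),
               My * b / cs$Iy, tolerance = 1e-6)
  # stress is zero on the neutral axis
  expect_equal(asymmetric_bending_stress(1, 0, cs, c(0.003, 0)), 0)
  # frame invariance: rotating the section and the moment vector together
  # leaves the stress at the co-rotated point unchanged
  rot <- 0.6
  cr <- section_properties(ellipse_poly(a, b, rot = rot))
  expect_gt(abs(cr$Iyz), 1e-12)        # genuinely asymmetric in this frame
  My0 <- 0.8; Mz0 <- -0.35
  p0 <- c(0.004, 0.002)
  R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2, 2)
  Mr <- as.numeric(R %*% c(My0, Mz0))
  pr <- as.numeric(R %*% p0)
  s0 <- asymmetric_bending_stress(My0, Mz0, cs, p0)
  sr <- asymmetric_bending_stress(Mr[1], Mr[2], cr, pr)
  expect_equal(sr, s0, tolerance = 1e-6)
  bad <- cs; bad$Iyz <- sqrt(cs$Iy * cs$Iz) * 1.01
  expect_error(asymmetric_bending_stress(1, 0, bad, c(0, b)), "geometry")
})

test_that("section-modulus regression recovers exact power laws", {
  L <- c(0.05, 0.08, 0.12, 0.21)
  Z <- 2.5e-6 * L^3
  fit <- section_modulus_regression(L, Z, query = 0.1)
  expect_equal(fit$exponent, 3, tolerance = 1e-9)
  expect_equal(fit$prediction, 2.5e-6 * 0.1^3, tolerance = 1e-9)
  # query at an observed length returns the observation for a perfect fit
  expect_equal(section_modulus_regression(L, Z, query = 0.08)$prediction,
               Z[2], tolerance = 1e-9)
  expect_error(section_modulus_regression(c(0.1, 0.2), c(1e-6, 8e-6), 0.15),
               "at least 3")
  expect_error(section_modulus_regression(c(-0.1, 0.2, 0.3), Z[1:3], 0.15),
               "positive")
})

test_that("safety factors and strain conversion reproduce worked values", {
  expect_equal(safety_factor(56.2e6, 78.6e6), 1.40, tolerance = 0.005)
  expect_equal(safety_factor(159e6, 108e6), 0.68, tolerance = 0.005)
  expect_equal(safety_factor(50e6, 50e6), 1)
  expect_error(safety_factor(0, 78.6e6), "positive")
  expect_equal(strain_to_stress(1027e-6, 12.1e9), 12.4267e6, tolerance = 1e-4)
  expect_equal(strain_to_stress(0), 0)
  expect_equal(strain_to_stress(2 * 500e-6), 2 * strain_to_stress(500e-6))
})

test_that("joint reactions on a massless static chain balance the GRF", {
  m <- toy_model()
  n <- 5
  grf <- matrix(rep(c(1, -2, 10), each = n), n, 3)
  cop <- matrix(rep(c(0, -0.25, 0), each = n), n, 3)
  tr <- toy_trial(m, n = n, grf = grf, cop = cop)
  sol <- solve_trial(m, tr, config = local({
    cfg <- reserve_config(1); cfg$activation_min <- 0; cfg
  }))
  jr <- joint_reaction(m, sol, tr, quasistatic = TRUE)
  for (j in c("hip", "knee", "ankle"))
    for (i in seq_len(n))
      expect_equal(jr$joints[[j]]$force[i, ], -grf[i, ], tolerance = 1e-9)
})

test_that("an equal-and-opposite muscle pair within one segment changes nothing", {
  # two actuators pulling between the same two thigh points in opposite
  # order: their point forces cancel exactly
  p1 <- list(segment = "thigh", point = c(0, -0.02, 0.01))
  p2 <- list(segment = "thigh", point = c(0, -0.08, -0.01))
  a1 <- actuator("pair1", list(p1, p2), m_musc = 0.01, l0 = 0.02, fmax = 50)
  a2 <- actuator("pair2", list(p2, p1), m_musc = 0.01, l0 = 0.02, fmax = 50)
  m0 <- toy_model()
  m2 <- toy_model(list(a1, a2))
  n <- 3
  grf <- matrix(rep(c(0, 0, 5), each = n), n, 3)
  cop <- matrix(rep(c(0, -0.2, 0), each = n), n, 3)
  tr0 <- toy_trial(m0, n = n, grf = grf, cop = cop)
  tr2 <- toy_trial(m2, n = n, grf = grf, cop = cop)
  sol0 <- solve_trial(m0, tr0, config = local({
    cfg <- reserve_config(1); cfg$activation_min <- 0; cfg
  }))
  sol2 <- solve_trial(m2, tr2, config = local({
    cfg <- reserve_config(1); cfg$activation_min <- 0; cfg
  }))
  sol2$forces[] <- 40   # force the pair to a common tension
  jr0 <- joint_reaction(m0, sol0, tr0, quasistatic = TRUE)
  jr2 <- joint_reaction(m2, sol2, tr2, quasistatic = TRUE)
  expect_equal(jr2$joints$hip$force, jr0$joints$hip$force, tolerance = 1e-9)
  expect_equal(jr2$joints$hip$moment, jr0$joints$hip$moment, tolerance = 1e-9)
})

test_that("a single knee-spanning muscle loads the midshaft as r x F", {
  # straight muscle from the proximal thigh to the shank, crossing the
  # midshaft plane; no GRF, massless chain, neutral pose
  L1 <- 0.1
  act <- actuator("span",
                  list(list(segment = "thigh", point = c(0, -0.01, 0.02)),
                       list(segment = "shank", point = c(0, -0.05, 0.02))),
                  m_musc = 0.01, l0 = 0.02, fmax = 200)
  m <- toy_model(list(act), L1 = L1)
  n <- 3
  tr <- toy_trial(m, n = n, cop = matrix(0, n, 3))
  sol <- solve_trial(m, tr, config = local({
    cfg <- reserve_config(1); cfg$activation_min <- 0; cfg
  }))
  tension <- 80
  sol$forces[] <- tension
  jr <- joint_reaction(m, sol, tr, quasistatic = TRUE)
  # by hand: the path runs parallel to the bone at z = +0.02 and pierces the
  # plane at (0, -0.05, 0.02) in world (midshaft at (0, -0.05, 0)); the
  # tension pulls the distal body towards the proximal point (0, +1, 0).
  # Axial: F_dop = -(-tension * (0,1,0)) => F.x_hat(=(0,-1,0)) = -tension.
  expect_equal(unname(jr$midshaft[2, "Fx"]), -tension, tolerance = 1e-9)
  # moment about the midshaft origin: r x F with r = (0, 0, 0.02) and
  # F = (0, tension, 0) on the distal body gives (-0.02 tension, 0, 0) in
  # world axes; the distal-on-proximal convention flips the sign and the
  # midshaft y axis is -x_w at the neutral pose, so My = +0.02 tension
  expect_equal(unname(jr$midshaft[2, "My"]), 0.02 * tension, tolerance = 1e-9)
  expect_equal(unname(jr$midshaft[2, "Mx"]), 0, tolerance = 1e-9)
})

test_that("stress traces keep the tension/compression identities everywhere", {
  m <- generate_model(5.64, seed = 1)
  tr <- generate_trial(m, seed = 1)
  r <- run_individual(m, tr)
  st <- r$stresses$stresses
  expect_equal(st$sigma_tens, st$sigma_bend + st$sigma_ax)
  expect_equal(st$sigma_comp, -st$sigma_bend + st$sigma_ax)
  expect_true(all(st$sigma_bend >= 0))
  expect_equal(r$stresses$peak[["sigma_tens"]], max(st$sigma_tens))
})
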