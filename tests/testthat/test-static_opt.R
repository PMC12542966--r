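# Static optimization: closed-form Lagrange oracles, moment-balance
# residuals, reserve behaviour and summaries.

# Minimal single-dof problem: muscles crossing the knee hinge with
# controllable moment arms (via the insertion radius) and F_max values.
knee_muscles_model <- function(arms, fmaxs, L1 = 0.1) {
  acts <- lapply(seq_along(arms), function(i)
    actuator(paste0("m", i),
             list(list(segment = "thigh", point = c(0, -L1 + 0.06, 0)),
                  list(segment = "shank", point = c(0, -0.05, arms[i]))),
             m_musc = 0.01, l0 = 1, slack = 0, fmax = fmaxs[i],
             primary_segment = "thigh"))
  toy_model(acts, L1 = L1)
}

# Effective generalized gain (moment per unit activation) of each muscle
# about a coordinate at a pose (isometric, no passive force).
muscle_gains <- function(model, pose, coord, hill = hill_config(passive = FALSE)) {
  vapply(names(model$actuators), function(nm) {
    a <- model$actuators[[nm]]
    r <- moment_arm(model, pose, a, coord)
    ln <- (musculotendon_length(model, pose, a) - a$slack) / a$l0
    r * a$fmax * active_force_length(ln, hill)
  }, numeric(1))
}

test_that("solver matches the closed-form Lagrange solution on toy problems", {
  pose <- c(knee_ef = 0.9)
  cfg <- reserve_config(1)
  cfg$activation_min <- 0
  # the Lagrange oracle solves the hard equality-constrained problem; make
  # the reserve cost overwhelming so the soft solve coincides to 1e-8
  cfg$tau_opt_main <- 1e-6
  hill <- hill_config(passive = FALSE)
  # two identical muscles sharing the load: a_i proportional to r_i F_i
  m <- knee_muscles_model(arms = c(0.02, 0.02), fmaxs = c(100, 100))
  gains <- muscle_gains(m, pose, "knee_ef", hill)
  required <- c(knee_ef = 0.5 * sum(gains))   # within capacity
  st <- solve_timestep(m, pose, NULL, required, config = cfg, hill = hill,
                       use_velocity = FALSE)
  oracle <- lagrange_activation(gains, required)
  expect_equal(unname(st$activations), unname(oracle), tolerance = 1e-8)
  expect_equal(st$activations[[1]], st$activations[[2]], tolerance = 1e-10)
  # unequal effectiveness: activations in the ratio of the gains
  m2 <- knee_muscles_model(arms = c(0.02, 0.02), fmaxs = c(100, 200))
  g2 <- muscle_gains(m2, pose, "knee_ef", hill)
  req2 <- c(knee_ef = 0.25 * sum(g2))
  st2 <- solve_timestep(m2, pose, NULL, req2, config = cfg, hill = hill,
                        use_velocity = FALSE)
  expect_equal(unname(st2$activations), unname(lagrange_activation(g2, req2)),
               tolerance = 1e-8)
  expect_equal(st2$activations[[2]] / st2$activations[[1]], g2[[2]] / g2[[1]],
               tolerance = 1e-6)
  # three muscles
  m3 <- knee_muscles_model(arms = c(0.01, 0.02, 0.03),
                           fmaxs = c(300, 150, 100))
  g3 <- muscle_gains(m3, pose, "knee_ef", hill)
  req3 <- c(knee_ef = 0.3 * sum(g3))
  st3 <- solve_timestep(m3, pose, NULL, req3, config = cfg, hill = hill,
                        use_velocity = FALSE)
  expect_equal(unname(st3$activations), unname(lagrange_activation(g3, req3)),
               tolerance = 1e-8)
  # zero required moment with a zero activation floor: all zeros
  st0 <- solve_timestep(m, pose, NULL, c(knee_ef = 0), config = cfg,
                        hill = hill, use_velocity = FALSE)
  expect_equal(unname(st0$activations), c(0, 0), tolerance = 1e-10)
  expect_equal(st0$objective, 0, tolerance = 1e-12)
})

test_that("moment balance holds to 1e-6 at every accepted timestep", {
  m <- generate_model(5.64, seed = 1)
  tr <- generate_trial(m, seed = 1)
  trf <- attach_cop(m, filter_trial(tr))
  sol <- solve_trial(m, trf)
  expect_true(all(sol$residual <= 1e-6))
  # re-verify independently: moment arms x forces + reserves = moments
  poses <- sprawlsim:::trial_poses(m, trf)
  i <- 20L
  mc <- c("hip_ef", "hip_aa", "hip_lar", "knee_ef", "ankle_ef")
  delivered <- vapply(mc, function(cn) {
    sum(vapply(names(m$actuators), function(nm)
      moment_arm(m, poses[i, ], m$actuators[[nm]], cn) * sol$forces[i, nm],
      numeric(1))) + sol$reserves[i, cn]
  }, numeric(1))
  expect_equal(delivered, sol$moments$moments[i, mc], tolerance = 1e-6)
})

test_that("the solution is invariant to muscle ordering", {
  pose <- c(knee_ef = 0.9)
  cfg <- reserve_config(1); cfg$activation_min <- 0
  hill <- hill_config(passive = FALSE)
  m <- knee_muscles_model(arms = c(0.01, 0.025, 0.015), fmaxs = c(80, 40, 120))
  req <- c(knee_ef = 0.08)
  st <- solve_timestep(m, pose, NULL, req, config = cfg, hill = hill,
                       use_velocity = FALSE)
  perm <- c(3L, 1L, 2L)
  mp <- m
  mp$actuators <- m$actuators[perm]
  stp <- solve_timestep(mp, pose, NULL, req, config = cfg, hill = hill,
                        use_velocity = FALSE)
  expect_equal(stp$activations, st$activations[perm], tolerance = 1e-10)
})

test_that("reserves absorb exactly what muscles cannot produce", {
  pose <- c(knee_ef = 0.9)
  cfg <- reserve_config(1); cfg$activation_min <- 0
  cfg$tau_opt_main <- 1e-6
  hill <- hill_config(passive = FALSE)
  m <- knee_muscles_model(arms = c(0.02, 0.02), fmaxs = c(100, 100))
  gains <- muscle_gains(m, pose, "knee_ef", hill)
  capacity <- sum(gains)
  # demand beyond total capacity: both muscles saturate, reserve = shortfall
  req <- c(knee_ef = 2 * capacity)
  st <- solve_timestep(m, pose, NULL, req, config = cfg, hill = hill,
                       use_velocity = FALSE)
  expect_true(st$saturated)
  expect_equal(unname(st$activations), c(1, 1), tolerance = 1e-9)
  expect_equal(st$reserves[["knee_ef"]], capacity, tolerance = 1e-8)
  # demand solvable by muscles: reserve negligible relative to the moment
  req2 <- c(knee_ef = 0.3 * capacity)
  st2 <- solve_timestep(m, pose, NULL, req2, config = cfg, hill = hill,
                        use_velocity = FALSE)
  expect_lt(abs(st2$reserves[["knee_ef"]]) / req2[["knee_ef"]], 1e-4)
})

test_that("extra capacity never increases the objective", {
  pose <- c(knee_ef = 0.9)
  cfg <- reserve_config(1); cfg$activation_min <- 0
  hill <- hill_config(passive = FALSE)
  req <- c(knee_ef = 0.6)
  objs <- vapply(c(100, 150, 220, 400), function(f1) {
    m <- knee_muscles_model(arms = c(0.02, 0.02), fmaxs = c(f1, 100))
    solve_timestep(m, pose, NULL, req, config = cfg, hill = hill,
                   use_velocity = FALSE)$objective
  }, numeric(1))
  expect_true(all(diff(objs) <= 1e-10))
})

test_that("reserve ratio diagnoses capacity deficits at the moment peak", {
  m <- knee_muscles_model(arms = c(0.02, 0.02), fmaxs = c(4000, 4000))
  cfg <- reserve_config(1); cfg$activation_min <- 0
  cfg$tau_opt_main <- 1e-6
  hill <- hill_config(passive = FALSE)
  n <- 11
  coords <- model_coords(m)
  ang <- matrix(0, n, length(coords), dimnames = list(NULL, coords))
  ang[, "knee_ef"] <- sprawlsim:::rad2deg(0.9)
  grf <- matrix(rep(c(0, 0, 10), each = n), n, 3)
  cop <- matrix(rep(c(0, -0.25, 0), each = n), n, 3)
  tr <- gait_trial(seq(0, 0.5, length.out = n), ang, grf, cop, body_mass = 1)
  id <- inverse_dynamics(m, tr, quasistatic = TRUE)
  sol <- solve_trial(m, tr, moments = id, config = cfg, hill = hill,
                     use_velocity = FALSE)
  # constant-pose, constant-moment trial: constant activation trace
  expect_lt(max(apply(sol$activations, 2, function(x) diff(range(x)))), 1e-8)
  rr <- reserve_ratio(sol, id, "knee_ef")
  expect_lt(rr, 1e-4)      # within capacity: essentially no reserve
  # muscles effectively disabled: the reserve carries the whole moment
  m0 <- knee_muscles_model(arms = c(0.02, 0.02), fmaxs = c(1e-9, 1e-9))
  sol0 <- solve_trial(m0, tr, moments = id, config = cfg, hill = hill,
                      use_velocity = FALSE)
  expect_equal(reserve_ratio(sol0, id, "knee_ef"), 1, tolerance = 1e-6)
  # half-capacity model: ratio 0.5
  pose <- c(knee_ef = 0.9)
  gains <- muscle_gains(m, pose, "knee_ef", hill)
  peak <- abs(id$peak_moment[["knee_ef"]])
  mh <- knee_muscles_model(arms = c(0.02, 0.02),
                           fmaxs = c(4000, 4000) * (peak / 2) / abs(sum(gains)))
  solh <- solve_trial(mh, tr, moments = id, config = cfg, hill = hill,
                      use_velocity = FALSE)
  expect_equal(reserve_ratio(solh, id, "knee_ef"), 0.5, tolerance = 1e-4)
  expect_error(reserve_ratio(sol, id, "hip_ef"), "undefined|zero")
})

test_that("activation summaries: midstance mean and stance peak", {
  n <- 101
  time <- seq(0, 1, length.out = n)
  sol <- structure(list(
    time = time,
    activations = cbind(const = rep(0.3, n), ramp = seq(0, 1, length.out = n))),
    class = "muscle_solution")
  s <- activation_summaries(sol)
  expect_equal(s$mean_midstance[s$muscle == "const"], 0.3)
  expect_equal(s$peak[s$muscle == "const"], 0.3)
  # linear ramp over stance: mean over [0.25, 0.75) is ~0.5 (half-open)
  expect_equal(s$mean_midstance[s$muscle == "ramp"], 0.495, tolerance = 1e-9)
  expect_equal(s$peak[s$muscle == "ramp"], 1)
  # half-open convention: the 0.75 sample is excluded
  tf <- (time - time[1]) / diff(range(time))
  expect_equal(sum(tf >= 0.25 & tf < 0.75), 50)
})
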