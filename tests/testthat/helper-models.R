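# Toy model builders used across the test files. All are valid four-segment
# chains so every pipeline stage accepts them; masses default to zero so
# statics are exact.

toy_dof <- function(name, axis, enabled = TRUE, sign = 1) {
  data.frame(name = name, axis = axis, enabled = enabled, sign = sign)
}

# Standard joint set of the generated models: translations + pitch/yaw at the
# ground, 3-dof hip, 1-dof knee and ankle. Lengths configurable.
toy_joints <- function(L1 = 0.1, L2 = 0.1, hip_origin = c(0, 0, 0),
                       ground_enabled = FALSE) {
  list(
    jcs("ground_body", "ground", "body", origin = c(0, 0, 0), triad = diag(3),
        dofs = rbind(toy_dof("body_tx", "tx", ground_enabled),
                     toy_dof("body_ty", "ty", ground_enabled),
                     toy_dof("body_tz", "tz", ground_enabled),
                     toy_dof("body_yaw", "z", ground_enabled),
                     toy_dof("body_pitch", "y", ground_enabled))),
    jcs("hip", "body", "thigh", origin = hip_origin,
        triad = cbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1)),
        dofs = rbind(toy_dof("hip_ef", "z"), toy_dof("hip_aa", "y"),
                     toy_dof("hip_lar", "x"))),
    jcs("knee", "thigh", "shank", origin = c(0, -L1, 0),
        triad = cbind(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0)),
        dofs = toy_dof("knee_ef", "z")),
    jcs("ankle", "shank", "foot", origin = c(0, -L2, 0),
        triad = cbind(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0)),
        dofs = toy_dof("ankle_ef", "z"))
  )
}

toy_segment <- function(name, mass = 0, com = c(0, 0, 0), inertia = NULL,
                        length = 0.1, landmarks = list()) {
  if (is.null(inertia)) inertia <- diag(3) * 0
  segment(name, mass = mass, com = com, inertia = inertia, length = length,
          landmarks = landmarks)
}

# Massless chain with foot landmarks; optional actuators.
toy_model <- function(actuators = list(), L1 = 0.1, L2 = 0.1, Lf = 0.06,
                      thigh_mass = 0, shank_mass = 0, foot_mass = 0,
                      thigh_inertia = NULL, shank_inertia = NULL,
                      ground_enabled = FALSE, body_mass = 1) {
  segs <- list(
    toy_segment("body", length = 0.2),
    toy_segment("thigh", mass = thigh_mass, com = c(0, -L1 / 2, 0),
                inertia = thigh_inertia, length = L1),
    toy_segment("shank", mass = shank_mass, com = c(0, -L2 / 2, 0),
                inertia = shank_inertia, length = L2),
    toy_segment("foot", mass = foot_mass, length = Lf,
                landmarks = list(ankle = c(0, 0, 0),
                                 mtp = c(0, -0.6 * Lf, 0),
                                 toe = c(0, -Lf, 0)))
  )
  msk_model(segs, toy_joints(L1, L2, ground_enabled = ground_enabled),
            actuators, body_mass = body_mass)
}

# A single actuator spanning the knee with a perpendicular insertion at
# radius r from the joint axis (planar moment-arm oracle).
toy_hinge_actuator <- function(r = 0.02, L1 = 0.1, fmax = 100) {
  actuator("hinge_m",
           list(list(segment = "thigh", point = c(0, -L1 + 0.05, 0)),
                list(segment = "shank", point = c(0, 0, r))),
           m_musc = 0.01, l0 = 0.02, slack = 0, fmax = fmax,
           primary_segment = "thigh")
}

# Constant-pose stance trial for a toy model (uniform sampling).
toy_trial <- function(model, n = 11, duration = 0.5, angles = NULL,
                      grf = NULL, cop = NULL, body_mass = model$body_mass) {
  time <- seq(0, duration, length.out = n)
  coords <- model_coords(model)
  if (is.null(angles)) {
    angles <- matrix(0, n, length(coords), dimnames = list(NULL, coords))
  }
  if (is.null(grf)) grf <- matrix(0, n, 3)
  gait_trial(time = time, angles = angles, grf = grf, cop = cop,
             body_mass = body_mass, duty_factor = 0.7)
}

# Closed-form minimum of sum a_i^2 subject to sum(c_i a_i) = M (Lagrange):
# a_i = M c_i / sum(c^2).
lagrange_activation <- function(cvec, M) M * cvec / sum(cvec^2)
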