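# Seeded synthetic-data generation: size- and posture-parameterized
# musculoskeletal models, stance-phase gait trials and annulus-like femoral
# cross-sections, emulating the statistical structure of size-structured
# gait experiments (GRF proportional to body weight, stance durations
# proportional to mass^(1/6), more crouched and abducted postures available
# as posture knobs) so that every pipeline stage runs without external data.

# Reference individual: a 5.64 kg juvenile (total length 1.28 m). All
# generated models are isometrically scaled from this description, with
# F_max scaled allometrically.
.ref_mass <- 5.64
.ref_dims <- list(
  body_length = 0.30, thigh = 0.075, shank = 0.065, foot = 0.075,
  # mass fractions (body carries the axial skeleton, tail and head)
  mass_frac = c(body = 0.925, thigh = 0.040, shank = 0.022, foot = 0.013)
)

# Reference muscle set: 12 actuators covering the functional groups of the
# crocodylian hindlimb. Path coordinates are local (m); bones run along -y.
# Belly masses (kg) and optimal fibre lengths (m) give F_max via the
# fibre-stress estimator. Circumferential offsets give the long-axis
# rotators their torsional moment arms.
.ref_muscles <- function() {
  thigh <- .ref_dims$thigh; shank <- .ref_dims$shank; foot <- .ref_dims$foot
  P <- function(seg, x, y, z) list(segment = seg, point = c(x, y, z))
  list(
    actuator("CFL", list(P("body", -0.11, 0.02, -0.008),
                         P("thigh", 0.004, -0.030, -0.006)),
             m_musc = 0.070, l0 = 0.055, primary_segment = "thigh",
             group = "hip extensor"),
    actuator("ADD1", list(P("body", 0.015, 0.004, -0.024),
                          P("thigh", 0.000, -0.038, -0.007)),
             m_musc = 0.032, l0 = 0.034, primary_segment = "thigh",
             group = "hip adductor"),
    actuator("ADD2", list(P("body", -0.012, 0.004, -0.022),
                          P("thigh", 0.000, -0.050, -0.006)),
             m_musc = 0.028, l0 = 0.036, primary_segment = "thigh",
             group = "hip adductor"),
    actuator("IFE", list(P("body", 0.0, 0.006, 0.024),
                         P("thigh", 0.000, -0.030, 0.007)),
             m_musc = 0.018, l0 = 0.030, primary_segment = "thigh",
             group = "hip abductor"),
    actuator("PIFI", list(P("body", 0.055, 0.010, 0.006),
                          P("thigh", 0.003, -0.022, 0.004)),
             m_musc = 0.036, l0 = 0.040, primary_segment = "thigh",
             group = "hip flexor"),
    actuator("ISTR", list(P("body", -0.020, 0.008, -0.014),
                          P("thigh", 0.013, -0.028, 0.000)),
             m_musc = 0.050, l0 = 0.030, primary_segment = "thigh",
             group = "hip medial rotator"),
    actuator("OTR", list(P("body", 0.020, 0.008, -0.014),
                         P("thigh", -0.013, -0.028, 0.000)),
             m_musc = 0.030, l0 = 0.030, primary_segment = "thigh",
             group = "hip lateral rotator"),
    # the knee extensor rides over a supracondylar via point directly above
    # the joint centre (patellar-groove analogue), keeping its extensor
    # moment arm at deep flexion; the flexor runs straight on the ventral
    # side from the proximal femur
    actuator("FTE", list(P("thigh", 0.002, -0.030, 0.008),
                         P("thigh", 0.002, -thigh, 0.018),
                         P("shank", 0.000, -0.008, 0.012)),
             m_musc = 0.040, l0 = 0.030, primary_segment = "thigh",
             group = "knee extensor"),
    actuator("FTI", list(P("thigh", 0.002, -0.035, -0.008),
                         P("shank", 0.000, -0.012, -0.009)),
             m_musc = 0.020, l0 = 0.030, primary_segment = "thigh",
             group = "knee flexor"),
    # plantarflexors route over a calcaneal-tuber (heel) point projecting
    # opposite the toes, the crocodylian Achilles lever
    actuator("GAST", list(P("shank", 0.000, -0.008, -0.007),
                          P("foot", -0.013, 0.010, -0.006)),
             m_musc = 0.034, l0 = 0.025, primary_segment = "shank",
             group = "ankle plantarflexor"),
    actuator("FDL", list(P("shank", 0.002, -0.012, -0.006),
                         P("foot", -0.010, 0.008, -0.005),
                         P("foot", 0.030, -0.015, -0.004)),
             m_musc = 0.014, l0 = 0.028, primary_segment = "shank",
             group = "ankle plantarflexor"),
    actuator("TA", list(P("shank", 0.000, -0.015, 0.006),
                        P("foot", 0.000, -0.012, 0.006)),
             m_musc = 0.008, l0 = 0.024, primary_segment = "shank",
             group = "ankle dorsiflexor")
  )
}

# Rod-like inertia tensor for a segment of mass m and length L along -y.
rod_inertia <- function(m, L) {
  i <- m * L^2 / 12
  diag(c(i, m * (0.2 * L)^2 / 2, i))
}

#' Generate a synthetic musculoskeletal model
#'
#' Builds the four-segment hindlimb chain (3-dof hip, 1-dof knee and ankle,
#' residual-bearing ground-body joint with translations plus pitch/yaw) with
#' the reference 12-muscle set covering the major functional groups,
#' isometrically scaled from the documented 5.64 kg reference individual:
#' lengths scale as (mass/5.64)^(1/3) and `F_max` as (mass/5.64)^b. Tendon
#' slack lengths are tuned so each fibre operates at the target normalized
#' length at the reference mid-stance pose.
#'
#' @param mass body mass (kg).
#' @param seed integer seed (recorded in the model; generation itself is
#'   deterministic given the arguments).
#' @param fmax_exponent allometric exponent for `F_max`.
#' @param n_muscles number of actuators (8 to 36); beyond the 12 reference
#'   muscles, additional actuators are split off the largest reference
#'   muscles with their belly mass shared.
#' @param slack_target target normalized fibre length for tendon slack
#'   tuning at the reference mid-stance pose.
#' @return a [msk_model()].
#' @export
generate_model <- function(mass, seed = 1L, fmax_exponent = 0.67,
                           n_muscles = 12L, slack_target = 1) {
  if (mass <= 0) stop("mass must be > 0")
  if (n_muscles < 8L || n_muscles > 36L)
    stop("n_muscles must lie between 8 and 36")
  d <- .ref_dims
  mf <- d$mass_frac
  segs <- list(
    segment("body", mass = .ref_mass * mf[["body"]], com = c(-0.05, 0.01, 0),
            inertia = rod_inertia(.ref_mass * mf[["body"]], d$body_length),
            length = d$body_length,
            landmarks = list(snout = c(0.12, 0.01, 0.01),
                             vent = c(-0.15, 0.01, -0.01))),
    segment("thigh", mass = .ref_mass * mf[["thigh"]],
            com = c(0, -d$thigh / 2, 0),
            inertia = rod_inertia(.ref_mass * mf[["thigh"]], d$thigh),
            length = d$thigh,
            landmarks = list(knee_marker = c(0, -d$thigh, 0.008))),
    segment("shank", mass = .ref_mass * mf[["shank"]],
            com = c(0, -d$shank / 2, 0),
            inertia = rod_inertia(.ref_mass * mf[["shank"]], d$shank),
            length = d$shank,
            landmarks = list(ankle_marker = c(0, -d$shank, 0.006))),
    segment("foot", mass = .ref_mass * mf[["foot"]],
            com = c(0.01, -d$foot / 2, 0),
            inertia = rod_inertia(.ref_mass * mf[["foot"]], d$foot),
            length = d$foot,
            # the foot long axis sweeps anterolaterally (60 deg from the
            # limb axis, i.e. mostly cranial) so the CoP path has a cranial
            # offset from the limb plane, loading the femur in torsion
            landmarks = list(
              ankle = c(0, 0, 0),
              mtp = c(0.6 * d$foot * sin(deg2rad(60)),
                      -0.6 * d$foot * cos(deg2rad(60)), 0),
              toe = c(d$foot * sin(deg2rad(60)),
                      -d$foot * cos(deg2rad(60)), 0)))
  )
  dof <- function(name, axis, enabled = TRUE, sign = 1)
    data.frame(name = name, axis = axis, enabled = enabled, sign = sign)
  joints <- list(
    jcs("ground_body", "ground", "body", origin = c(0, 0, 0), triad = diag(3),
        dofs = rbind(dof("body_tx", "tx"), dof("body_ty", "ty"),
                     dof("body_tz", "tz"), dof("body_yaw", "z"),
                     dof("body_pitch", "y"),
                     dof("body_roll", "x", enabled = FALSE))),
    # hip triad: z vertical (extension-flexion sweep), y cranial
    # (abduction-adduction; positive = adduction, femur depressed towards
    # erect), x lateral along the femur (long-axis rotation)
    jcs("hip", "body", "thigh", origin = c(0, -0.03, 0),
        triad = cbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1)),
        dofs = rbind(dof("hip_ef", "z"), dof("hip_aa", "y"),
                     dof("hip_lar", "x"))),
    # knee and ankle: pure extension-flexion about the cranial axis
    # (positive = flexion, distal segment depressed)
    jcs("knee", "thigh", "shank", origin = c(0, -d$thigh, 0),
        triad = cbind(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0)),
        dofs = dof("knee_ef", "z")),
    jcs("ankle", "shank", "foot", origin = c(0, -d$shank, 0),
        triad = cbind(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0)),
        dofs = dof("ankle_ef", "z"))
  )
  acts <- .ref_muscles()
  if (n_muscles < 12L) acts <- acts[seq_len(n_muscles)]
  if (n_muscles > 12L) {
    # split the largest bellies into parallel heads until the count is met
    extra <- n_muscles - 12L
    ord <- order(vapply(acts, `[[`, numeric(1L), "m_musc"), decreasing = TRUE)
    for (k in seq_len(extra)) {
      src <- acts[[ord[(k - 1L) %% 12L + 1L]]]
      head <- src
      head$name <- paste0(src$name, "_h", k)
      head$m_musc <- src$m_musc / 2
      acts <- c(acts, list(head))
    }
  }
  base <- msk_model(segs, joints, acts, material = material_properties(),
                    body_mass = .ref_mass)
  # tune tendon slack at the reference mid-stance pose
  ref_pose <- reference_pose()
  base$actuators <- lapply(base$actuators, function(a) {
    a$slack <- tune_tendon_slack(base, a, ref_pose,
                                 target_l_norm = slack_target)
    a
  })
  k <- (mass / .ref_mass)^(1 / 3)
  model <- scale_model(base, scaling_spec(
    target_mass = mass,
    length_factors = c(body = k, thigh = k, shank = k, foot = k),
    fmax_exponent = fmax_exponent))
  model$seed <- as.integer(seed)
  model
}

# Mid-stance reference pose of the generator (radians). The strongly flexed
# knee brings the foot under the knee, as in sprawling-to-high-walk stances.
reference_pose <- function(hip_adduction = 30, knee_flexion = 80) {
  c(hip_ef = 0, hip_aa = deg2rad(hip_adduction),
    hip_lar = 0, knee_ef = deg2rad(knee_flexion),
    ankle_ef = -deg2rad(hip_adduction + knee_flexion) + deg2rad(15))
}

#' Generate a synthetic stance-phase gait trial
#'
#' Smooth sinusoid-plus-offset joint-angle trajectories whose posture knobs
#' are the hip abduction offset (positive = more sprawling: the mean hip
#' adduction angle decreases) and the knee flexion offset (positive = more
#' crouched). The vertical ground reaction force is a single-peak half-sine
#' whose impulse equals body weight times stance duration; fore-aft and
#' mediolateral components are configurable fractions of body weight. Stance
#' duration scales as (mass/5.64)^(1/6) and forward speed keeps dynamic
#' similarity. The CoP is attached with the standard model, and optional
#' Gaussian noise is added to markers (generated from forward kinematics)
#' and GRF.
#'
#' @param model a [generate_model()] result.
#' @param abduction_offset posture knob (deg); subtracted from the base
#'   30 deg mean hip adduction.
#' @param knee_offset posture knob (deg); added to the base 80 deg mean knee
#'   flexion. The default `NULL` applies the crouched-sprawling covariation
#'   of 1.5 deg extra knee flexion per degree of hip abduction, emulating
#'   the pattern that more sprawled (less adducted) postures are also more
#'   crouched; pass an explicit value to decouple the knobs.
#' @param duty_factor stance-to-stride ratio.
#' @param duration_ref stance duration of the reference individual (s).
#' @param rate sampling rate (Hz).
#' @param marker_noise,grf_noise Gaussian noise SDs (m; N).
#' @param seed integer seed for the noise generator.
#' @return a [gait_trial()] with CoP attached and markers included.
#' @export
generate_trial <- function(model, abduction_offset = 0, knee_offset = NULL,
                           duty_factor = 0.7, duration_ref = 0.45,
                           rate = 100, marker_noise = 0, grf_noise = 0,
                           seed = 1L) {
  if (is.null(knee_offset)) knee_offset <- 1.5 * abduction_offset
  mass <- model$body_mass
  kt <- (mass / .ref_mass)^(1 / 6)
  Tst <- duration_ref * kt
  time <- seq(0, Tst, by = 1 / (rate / kt))
  n <- length(time)
  tf <- time / Tst
  base_add <- 30 - abduction_offset
  base_knee <- 80 + knee_offset
  ang <- cbind(
    hip_ef = 20 - 40 * tf + 3 * sin(2 * pi * tf),
    hip_aa = base_add + 5 * sin(pi * tf),
    hip_lar = 8 * sin(2 * pi * tf),
    knee_ef = base_knee + 8 * sin(pi * tf) - 4 * tf,
    ankle_ef = -(base_add + base_knee) + 15 - 6 * tf
  )
  # place the body so the foot works at ground height, moving forward at a
  # dynamically similar speed
  mid <- reference_pose(base_add, base_knee)
  st <- forward_kinematics(model, mid)
  toe_z <- fk_point(st, "foot", model$segments$foot$landmarks$toe)[3L]
  speed <- 0.30 * kt
  body <- cbind(body_tx = speed * (time - Tst / 2), body_ty = 0,
                body_tz = -toe_z, body_yaw = 0, body_pitch = 0)
  g <- model$gravity
  Fz <- (pi / 2) * mass * g * sin(pi * tf)
  Fx <- -0.15 * mass * g * sin(2 * pi * tf)   # braking then propulsion
  Fy <- 0.08 * mass * g * sin(pi * tf)        # medial push
  grf <- cbind(Fx, Fy, Fz)
  set.seed(as.integer(seed))
  if (grf_noise > 0)
    grf <- grf + matrix(stats::rnorm(3L * n, 0, grf_noise), n, 3L)
  grf[, 3L] <- pmax(0, grf[, 3L])
  trial <- gait_trial(time = time, angles = cbind(body, ang), grf = grf,
                      body_mass = mass, duty_factor = duty_factor)
  # synthetic skin markers from forward kinematics (+ noise), for IK use
  poses <- trial_poses(model, trial)
  mk <- list(knee = c("thigh", "knee_marker"), ankle = c("shank", "ankle_marker"),
             mtp = c("foot", "mtp"), toe = c("foot", "toe"),
             snout = c("body", "snout"), vent = c("body", "vent"))
  markers <- lapply(mk, function(m) {
    traj <- t(vapply(seq_len(n), function(i) {
      sti <- forward_kinematics(model, poses[i, ])
      fk_point(sti, m[1L], model$segments[[m[1L]]]$landmarks[[m[2L]]])
    }, numeric(3L)))
    if (marker_noise > 0)
      traj <- traj + matrix(stats::rnorm(3L * n, 0, marker_noise), n, 3L)
    attr(traj, "segment") <- m[1L]
    attr(traj, "point") <- model$segments[[m[1L]]]$landmarks[[m[2L]]]
    traj
  })
  trial$markers <- markers
  trial$seed <- as.integer(seed)
  attach_cop(model, trial)
}

#' Generate an annulus-like femoral cross-section polygon
#'
#' Elliptical annulus whose outer dorsoventral semi-axis is 6% of femur
#' length, with mediolateral semi-axis scaled by `eccentricity`, cortical
#' wall thickness a fraction of the outer semi-axis, and an optional
#' low-amplitude seeded radial perturbation.
#'
#' @param femur_length femur (thigh) length (m).
#' @param eccentricity mediolateral over dorsoventral semi-axis ratio.
#' @param thickness_frac cortical thickness as a fraction of the outer
#'   semi-axis, in `(0, 1)`.
#' @param perturb relative amplitude of the radial perturbation.
#' @param n_vertices polygon resolution.
#' @param seed integer seed for the perturbation.
#' @return list with `outer` and `inner` polygons (n x 2, metres, section
#'   y-z plane), ready for [section_properties()].
#' @export
generate_cross_section <- function(femur_length, eccentricity = 1.15,
                                   thickness_frac = 0.35, perturb = 0,
                                   n_vertices = 180L, seed = 1L) {
  if (femur_length <= 0 || eccentricity <= 0 || thickness_frac <= 0)
    stop("cross-section parameters must be positive")
  if (thickness_frac >= 1)
    stop("cortical thickness fraction must be below 1")
  b <- 0.06 * femur_length            # dorsoventral outer semi-axis
  a <- eccentricity * b               # mediolateral outer semi-axis
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  set.seed(as.integer(seed))
  bump <- if (perturb > 0) {
    ph <- stats::runif(3L, 0, 2 * pi)
    amp <- perturb * stats::runif(3L, 0.3, 1)
    1 + amp[1L] * cos(2 * th + ph[1L]) + amp[2L] * cos(3 * th + ph[2L]) +
      amp[3L] * cos(4 * th + ph[3L])
  } else 1
  outer <- cbind(a * cos(th) * bump, b * sin(th) * bump)
  inner <- cbind(a * (1 - thickness_frac) * cos(th) * bump,
                 b * (1 - thickness_frac) * sin(th) * bump)
  list(outer = outer, inner = inner)
}

#' Cohort specification for synthetic experiments
#'
#' @param individuals data frame with columns `id`, `mass` (kg),
#'   `abduction_offset` (deg), `knee_offset` (deg), `duty_factor`, `seed`.
#' @param marker_noise,grf_noise Gaussian noise SDs (m; N).
#' @param duration_ref reference stance duration (s); `rate` sampling rate
#'   (Hz).
#' @param fmax_exponent allometric F_max exponent used for all individuals.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(individuals, marker_noise = 0.001, grf_noise = 0.1,
                        duration_ref = 0.45, rate = 100,
                        fmax_exponent = 0.67) {
  stopifnot(is.data.frame(individuals),
            all(c("id", "mass") %in% names(individuals)))
  if (any(individuals$mass <= 0)) stop("masses must be > 0")
  defaults <- list(abduction_offset = 0, knee_offset = NA_real_,
                   duty_factor = 0.7, seed = seq_len(nrow(individuals)))
  for (nm in names(defaults))
    if (is.null(individuals[[nm]])) individuals[[nm]] <- defaults[[nm]]
  if (any(individuals$duty_factor <= 0 | individuals$duty_factor > 1))
    stop("duty factors must lie in (0, 1]")
  structure(list(individuals = individuals, marker_noise = marker_noise,
                 grf_noise = grf_noise, duration_ref = duration_ref,
                 rate = rate, fmax_exponent = fmax_exponent),
            class = "cohort_spec")
}
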