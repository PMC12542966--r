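# Per-timestep muscle-redundancy resolution: minimize the sum of squared
# activations plus squared normalized reserve/residual activations, subject
# to joint-moment balance with box bounds on muscle activations.
#
# With reserve torques tau_j = M_j - p_j - (R a)_j eliminated analytically,
# the problem is a strictly convex box-constrained quadratic program in the
# activations alone:
#   min  a'a + (b - R a)' W (b - R a),   l <= a <= u,
# with W = diag(1/tau_opt^2). It is solved exactly by a primal active-set
# iteration on the bounds (deterministic, warm-startable).

#' Reserve and residual actuator configuration
#'
#' Optimal reserve torques follow the mass scaling m^(4/3) g / 2000 for hip
#' extension-flexion, hip abduction-adduction and knee/ankle
#' extension-flexion, and m^(4/3) g / 4000 for femoral long-axis rotation,
#' imposing a high activation cost so that reserves engage only when muscle
#' capacity is insufficient. Residual actuators (body forces and the
#' pitch/yaw torques of the ground-body joint) have configurable optimal
#' values; they do not interact with the muscle solution because no muscle
#' can act on those coordinates.
#'
#' @param mass body mass (kg).
#' @param gravity gravitational acceleration (m s^-2).
#' @param lar_coords coordinate names costed at the m^(4/3) g / 4000 scale
#'   (femoral long-axis rotation).
#' @param residual_force_opt optimal residual force (N); default body weight.
#' @param residual_torque_opt optimal residual torque (N m).
#' @param activation_min hard lower activation bound (default 0.01).
#' @param activation_default warm-start activation for the first timestep
#'   (default 0.05).
#' @return an object of class `ss_reserve_config`.
#' @export
reserve_config <- function(mass, gravity = 9.81, lar_coords = "hip_lar",
                           residual_force_opt = mass * gravity,
                           residual_torque_opt = mass^(4 / 3) * gravity / 2000,
                           activation_min = 0.01,
                           activation_default = 0.05) {
  base <- mass^(4 / 3) * gravity
  structure(list(tau_opt_main = base / 2000, tau_opt_lar = base / 4000,
                 lar_coords = lar_coords,
                 residual_force_opt = residual_force_opt,
                 residual_torque_opt = residual_torque_opt,
                 activation_min = activation_min,
                 activation_default = activation_default),
            class = "ss_reserve_config")
}

# Optimal reserve/residual value per coordinate.
reserve_tau_opt <- function(config, coords, translational) {
  vapply(coords, function(cn) {
    if (cn %in% translational) config$residual_force_opt
    else if (grepl("^body_", cn)) config$residual_torque_opt
    else if (cn %in% config$lar_coords) config$tau_opt_lar
    else config$tau_opt_main
  }, numeric(1L))
}

# Exact active-set solve of
#   min a'a + (b - R a)' W (b - R a),  lower <= a <= upper.
# R: ndof x nmusc, b: ndof, wts: ndof (diagonal of W).
qp_activations <- function(R, b, wts, lower, upper, a0 = NULL,
                           max_iter = 200L) {
  nm <- ncol(R)
  sw <- sqrt(wts)
  # stacked least-squares form: minimize ||S a - t||^2 with
  # S = [sqrt(W) R; I], t = [sqrt(W) b; 0] -- numerically preferable to the
  # normal equations when reserve weights are large
  S <- rbind(R * sw, diag(nm))
  tvec <- c(sw * b, rep(0, nm))
  a <- if (is.null(a0)) pmin(upper, pmax(lower, rep(0, nm))) else
    pmin(upper, pmax(lower, a0))
  state <- integer(nm)  # 0 free, -1 at lower, +1 at upper
  for (it in seq_len(max_iter)) {
    free <- state == 0L
    if (any(free)) {
      rhs <- tvec - if (any(!free))
        S[, !free, drop = FALSE] %*% a[!free] else 0
      a[free] <- qr.solve(S[, free, drop = FALSE], rhs)
    }
    viol_lo <- free & (a < lower - 1e-12)
    viol_hi <- free & (a > upper + 1e-12)
    if (any(viol_lo) || any(viol_hi)) {
      state[viol_lo] <- -1L
      state[viol_hi] <- 1L
      a[viol_lo] <- lower[viol_lo]
      a[viol_hi] <- upper[viol_hi]
      next
    }
    # KKT on the bounds: g = 2a - 2 R' W (b - R a);
    # at the lower bound need g >= 0, at the upper g <= 0
    g <- 2 * a - 2 * as.numeric(crossprod(R, wts * (b - as.numeric(R %*% a))))
    rel_lo <- state == -1L & g < -1e-10
    rel_hi <- state == 1L & g > 1e-10
    if (!any(rel_lo) && !any(rel_hi)) break
    state[rel_lo | rel_hi] <- 0L
  }
  a
}

#' Solve the muscle redundancy problem at one timestep
#'
#' Minimizes the sum of squared muscle activations plus squared normalized
#' reserve/residual values, subject to exact joint-moment balance
#' (reserves absorb whatever the muscles do not produce):
#' \deqn{\min \sum_i a_i^2 + \sum_j (\tau_j/\tau_{opt,j})^2
#'   \quad s.t.\quad \sum_i r_{ij} F_i(a_i) + \tau_j = M_j,\;
#'   a_i \in [a_{min}, 1].}
#'
#' @param model a [msk_model()].
#' @param pose named pose vector (radians/metres).
#' @param velocities named vector of coordinate velocities (rad/s), used for
#'   fibre-velocity estimation; may be `NULL` (isometric).
#' @param required named vector of required generalized moments per enabled
#'   coordinate (from [inverse_dynamics()]).
#' @param config a [reserve_config()].
#' @param hill a [hill_config()].
#' @param a0 warm-start activation vector.
#' @param use_velocity logical; apply the force-velocity factor.
#' @return list with `activations` (named), `forces` (N), `reserves` (named
#'   per coordinate), `objective`, `residual` (moment-balance residual after
#'   reserves, identically ~0 by construction), `saturated` (logical: any
#'   muscle at its upper bound).
#' @export
solve_timestep <- function(model, pose, velocities = NULL, required,
                           config = reserve_config(model$body_mass,
                                                   model$gravity),
                           hill = hill_config(), a0 = NULL,
                           use_velocity = TRUE) {
  acts <- model$actuators
  nm <- length(acts)
  coords <- names(required)
  trans <- translational_coords(model)
  muscle_coords <- setdiff(coords, c(trans, grep("^body_", coords,
                                                 value = TRUE)))
  # kinematic state per muscle
  lnorm <- vapply(acts, function(a) normalized_fiber_length(model, pose, a),
                  numeric(1L))
  vnormv <- rep(0, nm)
  if (use_velocity && !is.null(velocities) && any(velocities != 0)) {
    h <- 1e-5
    pose2 <- pose
    for (cn in names(velocities))
      pose2[[cn]] <- (pose[[cn]] %||% 0) + velocities[[cn]] * h
    l2 <- vapply(acts, function(a) normalized_fiber_length(model, pose2, a),
                 numeric(1L))
    vnormv <- (l2 - lnorm) / h / hill$vmax_l0  # fibre lengths/s -> normalized
  }
  fl <- active_force_length(pmax(0, lnorm), hill)
  fv <- force_velocity(vnormv, hill)
  fp <- if (hill$passive) passive_force_length(lnorm, hill) else rep(0, nm)
  fmax <- vapply(acts, `[[`, numeric(1L), "fmax")
  gain <- fmax * fl * fv           # dF/da per muscle
  passive_force <- fmax * fp
  # moment-arm matrix over muscle-actuated coordinates
  Rarm <- matrix(0, length(muscle_coords), nm,
                 dimnames = list(muscle_coords, names(acts)))
  for (j in seq_along(muscle_coords))
    for (i in seq_len(nm))
      Rarm[j, i] <- moment_arm(model, pose, acts[[i]], muscle_coords[j])
  Rgain <- Rarm * rep(gain, each = nrow(Rarm))
  b <- required[muscle_coords] - as.numeric(Rarm %*% passive_force)
  tau_opt <- reserve_tau_opt(config, coords, trans)
  wts <- 1 / tau_opt[muscle_coords]^2
  lower <- rep(config$activation_min, nm)
  upper <- rep(1, nm)
  a <- qp_activations(Rgain, b, wts, lower, upper, a0 = a0)
  forces <- gain * a + passive_force
  reserves <- stats::setNames(numeric(length(coords)), coords)
  reserves[muscle_coords] <- b - as.numeric(Rgain %*% a)
  other <- setdiff(coords, muscle_coords)
  reserves[other] <- required[other]   # residuals take these entirely
  objective <- sum(a^2) + sum((reserves / tau_opt[coords])^2)
  delivered <- as.numeric(Rarm %*% forces) + reserves[muscle_coords]
  residual <- max(abs(delivered - required[muscle_coords]) /
                    pmax(1, abs(required[muscle_coords])))
  list(activations = stats::setNames(a, names(acts)),
       forces = stats::setNames(forces, names(acts)),
       reserves = reserves, objective = objective, residual = residual,
       saturated = any(a >= 1 - 1e-9),
       l_norm = stats::setNames(lnorm, names(acts)),
       v_norm = stats::setNames(vnormv, names(acts)))
}

#' Solve static optimization over a full stance trial
#'
#' Applies [solve_timestep()] at every stance sample, warm-starting each
#' solve from the previous timestep (the first from the default activation).
#' Coordinate velocities come from central differences of the pose
#' trajectories.
#'
#' @param model a [msk_model()].
#' @param trial a preprocessed [gait_trial()] (filtered angles, CoP).
#' @param moments an `ss_moment_trace` from [inverse_dynamics()]; computed
#'   on the fly when `NULL`.
#' @param config a [reserve_config()]; `hill` a [hill_config()].
#' @param quasistatic passed to [inverse_dynamics()] when moments are
#'   computed here.
#' @param use_velocity logical; apply the force-velocity factor.
#' @return an object of class `muscle_solution`: activation/force matrices
#'   (n x n_muscle), reserve matrix (n x n_coord), objective and residual
#'   traces, saturation flags, and the moment trace used.
#' @export
solve_trial <- function(model, trial, moments = NULL,
                        config = reserve_config(model$body_mass,
                                                model$gravity),
                        hill = hill_config(), quasistatic = FALSE,
                        use_velocity = TRUE) {
  if (is.null(moments)) moments <- inverse_dynamics(model, trial, quasistatic)
  if (!identical(length(trial$time), length(moments$time)))
    stop("trial and moment trace have mismatched time vectors")
  poses <- trial_poses(model, trial)
  vels <- row_deriv(poses, trial$time)
  n <- length(trial$time)
  coords <- colnames(moments$moments)
  acts <- names(model$actuators)
  A <- matrix(0, n, length(acts), dimnames = list(NULL, acts))
  FF <- A
  RES <- matrix(0, n, length(coords), dimnames = list(NULL, coords))
  obj <- numeric(n); resid <- numeric(n); sat <- logical(n)
  a_prev <- rep(config$activation_default, length(acts))
  for (i in seq_len(n)) {
    st <- solve_timestep(model, poses[i, ], vels[i, ],
                         required = moments$moments[i, ], config = config,
                         hill = hill, a0 = a_prev,
                         use_velocity = use_velocity)
    A[i, ] <- st$activations
    FF[i, ] <- st$forces
    RES[i, ] <- st$reserves[coords]
    obj[i] <- st$objective
    resid[i] <- st$residual
    sat[i] <- st$saturated
    a_prev <- st$activations
  }
  structure(list(time = trial$time, activations = A, forces = FF,
                 reserves = RES, objective = obj, residual = resid,
                 saturated = sat, moments = moments, config = config),
            class = "muscle_solution")
}

#' @export
print.muscle_solution <- function(x, ...) {
  cat("Static-optimization solution: ", nrow(x$activations), " timesteps, ",
      ncol(x$activations), " muscles; peak activation ",
      format(max(x$activations), digits = 3), "; ",
      sum(x$saturated), " saturated step(s)\n", sep = "")
  invisible(x)
}

#' Reserve-to-external-moment ratio at the instant of peak moment
#'
#' @param solution a `muscle_solution`.
#' @param moments the `ss_moment_trace` used (defaults to the one stored in
#'   the solution).
#' @param coord coordinate name.
#' @return `|reserve| / |external moment|` evaluated at the time index of
#'   the coordinate's peak external moment.
#' @export
reserve_ratio <- function(solution, moments = solution$moments, coord) {
  idx <- moments$peak_index[[coord]]
  peak <- moments$moments[idx, coord]
  if (abs(peak) < 1e-12)
    stop("peak external moment for '", coord, "' is zero; ratio undefined")
  unname(abs(solution$reserves[idx, coord]) / abs(peak))
}

#' Per-muscle activation summaries over a stance window
#'
#' Means are taken over the half-open midstance window `[window[1],
#' window[2])` of stance fraction (documented convention); peaks over the
#' whole stance.
#'
#' @param solution a `muscle_solution`.
#' @param window stance-fraction window, default the 25--75% midstance.
#' @return data frame with `muscle`, `mean_midstance`, `peak`.
#' @export
activation_summaries <- function(solution, window = c(0.25, 0.75)) {
  tfrac <- (solution$time - solution$time[1L]) /
    diff(range(solution$time))
  sel <- tfrac >= window[1L] & tfrac < window[2L]
  data.frame(muscle = colnames(solution$activations),
             mean_midstance = colMeans(solution$activations[sel, , drop = FALSE]),
             peak = apply(solution$activations, 2L, max),
             row.names = NULL)
}
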