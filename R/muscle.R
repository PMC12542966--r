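# Hill-type musculotendon mechanics under the rigid-tendon convention:
# F_max estimation from muscle belly mass, active/passive force-length and
# force-velocity scale factors, path-based musculotendon lengths, moment arms
# by tendon excursion, and tendon slack length tuning.

#' Estimate maximal isometric force from muscle belly mass
#'
#' \deqn{F_{max} = m_{musc} \sigma / (\rho l_0)}
#' with \eqn{\sigma} the maximum fibre stress and \eqn{\rho} the muscle
#' density. Pennation angle is deliberately excluded.
#'
#' @param m_musc muscle belly mass (kg), non-negative.
#' @param l0 optimal fibre length (m), positive.
#' @param material a [material_properties()] object supplying `sigma_max` and
#'   `rho_muscle`.
#' @return maximal isometric force (N).
#' @export
estimate_fmax <- function(m_musc, l0, material = material_properties()) {
  if (any(!is.finite(l0)) || any(l0 <= 0))
    stop("optimal fiber length l0 must be > 0")
  if (any(m_musc < 0)) stop("muscle belly mass must be non-negative")
  m_musc * material$sigma_max / (material$rho_muscle * l0)
}

#' Default Hill-curve configuration
#'
#' Shapes of the dimensionless muscle curves. `fl_width` is the Gaussian
#' width of the active force-length curve; `fv_shape` the curvature of the
#' concentric Hill hyperbola; `fv_plateau` the eccentric asymptote;
#' `passive_gain` the quadratic gain of the passive curve above slack fibre
#' length; `vmax_l0` the maximum shortening velocity in optimal fibre lengths
#' per second, used to normalize fibre velocities.
#'
#' @param fl_width,fv_shape,fv_plateau,passive_gain,vmax_l0 curve parameters.
#' @param passive logical, include the passive fibre force in
#'   [muscle_force()].
#' @return list of curve parameters.
#' @export
hill_config <- function(fl_width = 0.45, fv_shape = 0.25, fv_plateau = 1.4,
                        passive_gain = 2, vmax_l0 = 10, passive = TRUE) {
  list(fl_width = fl_width, fv_shape = fv_shape, fv_plateau = fv_plateau,
       passive_gain = passive_gain, vmax_l0 = vmax_l0, passive = passive)
}

#' Active force-length scale factor
#'
#' Unimodal Gaussian bump with maximum 1 at normalized fibre length 1,
#' approaching 0 beyond filament overlap.
#'
#' @param l_norm normalized fibre length (fibre length / l0), non-negative.
#' @param config a [hill_config()].
#' @return scale factor in `[0, 1]`.
#' @export
active_force_length <- function(l_norm, config = hill_config()) {
  if (any(l_norm < 0)) stop("normalized fiber length must be non-negative")
  exp(-((l_norm - 1) / config$fl_width)^2)
}

#' Force-velocity scale factor
#'
#' Concentric side follows the Hill hyperbola, reaching 0 at the maximum
#' shortening velocity (`v_norm = -1`); isometric value is exactly 1;
#' lengthening rises monotonically towards the eccentric plateau.
#'
#' @param v_norm fibre velocity normalized by the maximum shortening
#'   velocity; negative = shortening.
#' @param config a [hill_config()].
#' @return non-negative scale factor.
#' @export
force_velocity <- function(v_norm, config = hill_config()) {
  k <- config$fv_shape
  ifelse(v_norm <= 0,
         pmax(0, (1 + v_norm) / (1 - v_norm / k)),
         1 + (config$fv_plateau - 1) * v_norm / (v_norm + 0.2))
}

#' Passive force-length scale factor
#'
#' Zero at and below the optimal fibre length, quadratic above.
#'
#' @inheritParams active_force_length
#' @return non-negative scale factor.
#' @export
passive_force_length <- function(l_norm, config = hill_config()) {
  ifelse(l_norm > 1, config$passive_gain * (l_norm - 1)^2, 0)
}

#' Musculotendon force under the rigid-tendon convention
#'
#' \deqn{F = F_{max} (a f_L(\tilde l) f_V(\tilde v) + f_P(\tilde l))}
#' with the passive term included only when `config$passive` is `TRUE`.
#'
#' @param activation activation in `[0, 1]`.
#' @param l_norm,v_norm normalized fibre length and velocity.
#' @param act an [actuator()] (supplies `fmax`).
#' @param config a [hill_config()].
#' @return force (N).
#' @export
muscle_force <- function(activation, l_norm, v_norm = 0, act,
                         config = hill_config()) {
  if (any(activation < -1e-12) || any(activation > 1 + 1e-12))
    stop("activation must lie in [0, 1]")
  pas <- if (config$passive) passive_force_length(l_norm, config) else 0
  act$fmax * (activation * active_force_length(l_norm, config) *
                force_velocity(v_norm, config) + pas)
}

# Geodesic detour of a straight path segment around a cylinder, following
# the usual obstacle-set construction: the wrap is solved in the plane
# perpendicular to the cylinder axis and the axial component is recovered by
# stretching the planar path. Returns the path length from p1 to p2.
wrap_segment_length <- function(p1, p2, center, axis, radius) {
  r1 <- p1 - center; r2 <- p2 - center
  q1 <- r1 - sum(r1 * axis) * axis  # planar components
  q2 <- r2 - sum(r2 * axis) * axis
  d1 <- vnorm(q1); d2 <- vnorm(q2)
  straight <- vnorm(p2 - p1)
  if (d1 <= radius || d2 <= radius) return(straight)  # endpoint inside: skip
  ang <- acos(pmin(1, pmax(-1, sum(q1 * q2) / (d1 * d2))))
  theta <- ang - acos(radius / d1) - acos(radius / d2)
  if (theta <= 0) return(straight)  # tangents do not touch the cylinder
  planar <- sqrt(d1^2 - radius^2) + radius * theta + sqrt(d2^2 - radius^2)
  dz <- sum((p2 - p1) * axis)
  sqrt(planar^2 + dz^2)
}

#' Musculotendon path length at a pose
#'
#' Sum of straight-line distances between consecutive path points after
#' forward-kinematic placement; when a cylindrical wrap primitive is present
#' its geodesic detour replaces the straight segment it is assigned to.
#'
#' @param model a [msk_model()].
#' @param pose named pose vector (radians / metres).
#' @param act an [actuator()] of the model.
#' @return path length (m).
#' @export
musculotendon_length <- function(model, pose, act) {
  states <- forward_kinematics(model, pose)
  pts <- lapply(act$path, function(p) {
    if (is.null(states[[p$segment]]))
      stop("path point on unknown segment '", p$segment, "'")
    fk_point(states, p$segment, p$point)
  })
  n <- length(pts)
  L <- 0
  for (i in seq_len(n - 1L)) {
    if (!is.null(act$wrap) && act$wrap$between[1L] == i) {
      w <- act$wrap
      cw <- fk_point(states, w$segment, w$center)
      aw <- as.numeric(states[[w$segment]]$R %*% w$axis)
      L <- L + wrap_segment_length(pts[[i]], pts[[i + 1L]], cw, aw, w$radius)
    } else {
      L <- L + vnorm(pts[[i + 1L]] - pts[[i]])
    }
  }
  L
}

#' Moment arm by tendon excursion
#'
#' \eqn{r = -\partial L / \partial \theta} evaluated by a central finite
#' difference on the musculotendon length, so that a positive moment arm
#' means the muscle generates a positive moment about the coordinate
#' (right-hand rule, virtual-work consistent).
#'
#' @param model a [msk_model()]; `pose` as in [forward_kinematics()].
#' @param pose named pose vector.
#' @param act an [actuator()].
#' @param coord generalized coordinate name.
#' @param h finite-difference step (rad).
#' @return moment arm (m).
#' @export
moment_arm <- function(model, pose, act, coord, h = 1e-4) {
  pp <- pose; pm <- pose
  base <- if (coord %in% names(pose)) pose[[coord]] else 0
  pp[[coord]] <- base + h
  pm[[coord]] <- base - h
  -(musculotendon_length(model, pp, act) -
      musculotendon_length(model, pm, act)) / (2 * h)
}

#' Tune tendon slack length to a target operating fibre length
#'
#' Under the rigid-tendon model the fibre length is the musculotendon length
#' minus the tendon slack length. The slack length is found by bisection so
#' that the fibre operates at `target_l_norm` at the reference pose (by
#' default the mean of the supplied reference poses).
#'
#' @param model a [msk_model()].
#' @param act an [actuator()].
#' @param reference_poses list of pose vectors spanning the stance range, or
#'   a single pose vector.
#' @param target_l_norm target normalized fibre length at the reference pose.
#' @param tol bisection tolerance on `|l_norm - target|`.
#' @return tendon slack length (m).
#' @export
tune_tendon_slack <- function(model, act, reference_poses,
                              target_l_norm = 1, tol = 1e-6) {
  if (!is.list(reference_poses)) reference_poses <- list(reference_poses)
  nm <- unique(unlist(lapply(reference_poses, names)))
  ref <- vapply(nm, function(k) mean(vapply(reference_poses, function(p)
    if (k %in% names(p)) p[[k]] else 0, numeric(1L))), numeric(1L))
  names(ref) <- nm
  lmt <- musculotendon_length(model, ref, act)
  f <- function(s) (lmt - s) / act$l0 - target_l_norm
  if (f(0) < 0 || f(lmt) > 0)
    stop("tendon slack tuning failed for actuator '", act$name,
         "': target normalized length ", target_l_norm,
         " unreachable within [0, ", format(lmt), "]")
  lo <- 0; hi <- lmt
  while (abs(f((lo + hi) / 2)) >= tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Normalized fibre length of an actuator at a pose (rigid tendon).
normalized_fiber_length <- function(model, pose, act) {
  (musculotendon_length(model, pose, act) - act$slack) / act$l0
}
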