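# Domain types for the hindlimb musculoskeletal model: segments, joint
# coordinate systems (JCS), material properties, and the assembled model.
#
# Conventions:
#   * Ground frame: right-handed, x cranial (direction of travel), y left,
#     z vertical (up).
#   * Neutral pose (all generalized coordinates zero): the limb is splayed
#     laterally and every segment's local frame is aligned with the ground
#     frame. Limb bones run along local -y (distal direction for the right
#     hindlimb).
#   * Joint rotations are intrinsic z-y-x in the JCS triad frame (right-hand
#     rule). Angles are stored in degrees in files and trial tables, radians
#     internally.

#' Construct a body segment
#'
#' @param name segment name, one of `"body"`, `"thigh"`, `"shank"`, `"foot"`.
#' @param mass segment mass (kg), non-negative.
#' @param com centre of mass in the segment's local frame (m), length-3.
#' @param inertia 3x3 inertia tensor about the centre of mass (kg m^2),
#'   symmetric positive semidefinite.
#' @param length characteristic segment length (m), used for scaling.
#' @param landmarks named list of length-3 local coordinates (m), e.g. the
#'   ankle, MTP-III and toe-tip markers on the foot.
#' @return an object of class `ss_segment`.
#' @export
segment <- function(name, mass, com = c(0, 0, 0), inertia = diag(3) * 0,
                    length = NA_real_, landmarks = list()) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(mass) || length(mass) != 1L || mass < 0)
    stop("segment mass must be a single non-negative number")
  inertia <- as.matrix(inertia)
  if (!all(dim(inertia) == c(3L, 3L)) || max(abs(inertia - t(inertia))) > 1e-12)
    stop("inertia tensor must be a symmetric 3x3 matrix")
  if (min(eigen(inertia, symmetric = TRUE, only.values = TRUE)$values) < -1e-12)
    stop("inertia tensor must be positive semidefinite")
  if (length(landmarks) && !all(vapply(landmarks, function(p)
    is.numeric(p) && length(p) == 3L && all(is.finite(p)), logical(1L))))
    stop("landmarks must be finite length-3 numeric vectors")
  structure(list(name = name, mass = mass, com = as.numeric(com),
                 inertia = inertia, length = length, landmarks = landmarks),
            class = "ss_segment")
}

#' Construct a joint coordinate system
#'
#' A JCS connects a parent to a child segment. Its triad gives the joint x, y
#' and z axes (columns, unit vectors) in the parent's local frame at the
#' neutral pose; rotations are applied intrinsically in the order z, y, x.
#'
#' @param name joint name (e.g. `"hip"`).
#' @param parent,child parent and child segment names (`"ground"` allowed as
#'   parent of the root joint).
#' @param origin joint centre in the parent's local frame (m).
#' @param triad 3x3 matrix, columns are the joint x, y, z axes in the parent
#'   frame; must be orthonormal and right-handed to 1e-9.
#' @param dofs data frame with columns `name` (globally unique coordinate
#'   name), `axis` (`"z"`, `"y"`, `"x"` for rotations in application order, or
#'   `"tx"`, `"ty"`, `"tz"` for translations along the triad axes), `enabled`
#'   (logical) and `sign` (+1/-1 right-hand-rule sign convention).
#' @return an object of class `ss_jcs`.
#' @export
jcs <- function(name, parent, child, origin = c(0, 0, 0), triad = diag(3),
                dofs) {
  triad <- as.matrix(triad)
  if (!is_orthonormal(triad, 1e-9))
    stop("JCS triad must be orthonormal and right-handed to 1e-9")
  stopifnot(is.data.frame(dofs),
            all(c("name", "axis", "enabled", "sign") %in% names(dofs)))
  if (!all(dofs$axis %in% c("x", "y", "z", "tx", "ty", "tz")))
    stop("dof axis must be one of x, y, z, tx, ty, tz")
  structure(list(name = name, parent = parent, child = child,
                 origin = as.numeric(origin), triad = triad,
                 rotation_order = c("z", "y", "x"), dofs = dofs),
            class = "ss_jcs")
}

#' Material properties of bone and muscle
#'
#' Defaults follow measured values for the American alligator femur
#' (elastic modulus 12.1 GPa; yield 78.6 MPa; ultimate 108 MPa) and standard
#' vertebrate muscle constants (maximum fibre stress 300 kPa, density
#' 1060 kg m^-3).
#'
#' @param E elastic modulus (Pa).
#' @param yield_stress yield stress (Pa).
#' @param ultimate_stress ultimate stress (Pa).
#' @param sigma_max maximum isometric muscle fibre stress (Pa).
#' @param rho_muscle muscle density (kg m^-3).
#' @return an object of class `ss_material`.
#' @export
material_properties <- function(E = 12.1e9, yield_stress = 78.6e6,
                                ultimate_stress = 108e6, sigma_max = 3.0e5,
                                rho_muscle = 1060) {
  vals <- c(E, yield_stress, ultimate_stress, sigma_max, rho_muscle)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all material properties must be strictly positive")
  if (yield_stress >= ultimate_stress)
    stop("yield stress must be below ultimate stress")
  structure(list(E = E, yield_stress = yield_stress,
                 ultimate_stress = ultimate_stress, sigma_max = sigma_max,
                 rho_muscle = rho_muscle),
            class = "ss_material")
}

#' Construct a musculotendon actuator
#'
#' A Hill-type actuator defined by an ordered geometric path of attachment and
#' via points, each owned by a segment, with an optional single cylindrical
#' wrap primitive.
#'
#' @param name actuator name.
#' @param path list of path points, each `list(segment =, point =)` with
#'   `point` a length-3 local coordinate (m); at least two points.
#' @param m_musc muscle belly mass (kg).
#' @param l0 optimal fibre length (m), positive.
#' @param pennation pennation angle (deg); stored as metadata only, it does
#'   not enter the force computation.
#' @param slack tendon slack length (m).
#' @param fmax maximal isometric force (N); if `NA`, computed from
#'   [estimate_fmax()] when the model is assembled.
#' @param primary_segment segment whose length scale governs this muscle's
#'   fibre and tendon lengths under model scaling.
#' @param group functional group label (e.g. `"hip extensor"`).
#' @param wrap optional cylindrical wrap:
#'   `list(segment =, center =, axis =, radius =, between = c(i, i + 1))`,
#'   applied to the path segment between points `i` and `i + 1`.
#' @return an object of class `ss_actuator`.
#' @export
actuator <- function(name, path, m_musc, l0, pennation = 0, slack = 0,
                     fmax = NA_real_, primary_segment = "thigh",
                     group = "other", wrap = NULL) {
  if (length(path) < 2L) stop("actuator path needs at least 2 points")
  ok <- vapply(path, function(p) is.list(p) && !is.null(p$segment) &&
                 is.numeric(p$point) && length(p$point) == 3L, logical(1L))
  if (!all(ok)) stop("each path point must be list(segment =, point =)")
  if (!is.finite(l0) || l0 <= 0) stop("optimal fiber length l0 must be > 0")
  if (m_musc < 0) stop("muscle belly mass must be non-negative")
  if (!primary_segment %in% c("body", "thigh", "shank", "foot"))
    stop("primary_segment must be one of body, thigh, shank, foot")
  if (!is.null(wrap)) {
    stopifnot(all(c("segment", "center", "axis", "radius", "between")
                  %in% names(wrap)))
    wrap$axis <- unit3(wrap$axis)
  }
  structure(list(name = name, path = path, m_musc = m_musc, l0 = l0,
                 pennation = pennation, slack = slack, fmax = fmax,
                 primary_segment = primary_segment, group = group,
                 wrap = wrap),
            class = "ss_actuator")
}

#' Assemble a musculoskeletal model
#'
#' Joins segments, joint coordinate systems and actuators into a validated
#' model of the chain ground -> body -> thigh -> shank -> foot. Actuators with
#' `fmax = NA` get it from [estimate_fmax()] using the model's material
#' constants.
#'
#' @param segments list of [segment()] objects (body, thigh, shank, foot).
#' @param joints list of [jcs()] objects in chain order from the ground joint.
#' @param actuators list of [actuator()] objects.
#' @param material a [material_properties()] object.
#' @param body_mass total body mass (kg).
#' @param gravity gravitational acceleration (m s^-2).
#' @return an object of class `msk_model`.
#' @export
msk_model <- function(segments, joints, actuators = list(),
                      material = material_properties(), body_mass,
                      gravity = 9.81) {
  names(segments) <- vapply(segments, `[[`, character(1L), "name")
  names(joints) <- vapply(joints, `[[`, character(1L), "name")
  names(actuators) <- vapply(actuators, `[[`, character(1L), "name")
  if (body_mass <= 0) stop("total body mass must be > 0")
  # chain validation: parents must precede children starting at ground
  known <- "ground"
  for (j in joints) {
    if (!j$parent %in% known)
      stop("joint graph must be a chain from ground: parent '", j$parent,
           "' of joint '", j$name, "' not yet placed")
    if (!j$child %in% names(segments))
      stop("joint child segment '", j$child, "' not found")
    known <- c(known, j$child)
  }
  if (!setequal(known, c("ground", names(segments))))
    stop("every segment must be connected by exactly one joint")
  for (a in actuators) {
    for (p in a$path)
      if (!p$segment %in% names(segments))
        stop("actuator '", a$name, "' references unknown segment '",
             p$segment, "'")
  }
  m <- structure(list(segments = segments, joints = joints,
                      actuators = actuators, material = material,
                      body_mass = body_mass, gravity = gravity),
                 class = "msk_model")
  # fill in missing F_max from the muscle-mass estimator
  m$actuators <- lapply(m$actuators, function(a) {
    if (is.na(a$fmax)) a$fmax <- estimate_fmax(a$m_musc, a$l0, material)
    if (a$fmax <= 0) stop("actuator '", a$name, "' has non-positive F_max")
    a
  })
  m
}

#' @export
print.msk_model <- function(x, ...) {
  cat("Musculoskeletal model: ", length(x$segments), " segments, ",
      length(x$joints), " joints, ", length(x$actuators),
      " musculotendon actuators\n", sep = "")
  cat("  body mass ", format(x$body_mass), " kg; coordinates: ",
      paste(model_coords(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Generalized coordinate names of a model
#'
#' @param model a [msk_model()].
#' @return character vector of enabled coordinate names, in chain order.
#' @export
model_coords <- function(model) {
  unlist(lapply(model$joints, function(j) j$dofs$name[j$dofs$enabled]),
         use.names = FALSE)
}

# Angles (radians) for the z-y-x rotation of one joint, given a pose vector.
joint_zyx_angles <- function(j, pose) {
  ang <- c(z = 0, y = 0, x = 0)
  rot <- j$dofs[j$dofs$axis %in% c("z", "y", "x"), , drop = FALSE]
  for (k in seq_len(nrow(rot))) {
    d <- rot[k, ]
    if (d$enabled && d$name %in% names(pose))
      ang[d$axis] <- pose[[d$name]] * d$sign
  }
  ang
}

joint_translation <- function(j, pose) {
  tr <- c(0, 0, 0)
  tdof <- j$dofs[j$dofs$axis %in% c("tx", "ty", "tz"), , drop = FALSE]
  for (k in seq_len(nrow(tdof))) {
    d <- tdof[k, ]
    if (d$enabled && d$name %in% names(pose)) {
      ax <- match(substring(d$axis, 2L), c("x", "y", "z"))
      tr <- tr + j$triad[, ax] * pose[[d$name]] * d$sign
    }
  }
  tr
}

#' Forward kinematics
#'
#' Places every segment frame in the ground frame for a given pose.
#'
#' @param model a [msk_model()].
#' @param pose named numeric vector of generalized coordinates (radians for
#'   rotations, metres for translations); missing coordinates are taken as 0.
#' @return named list with one element per segment:
#'   `list(R = 3x3 orientation, p = origin in ground frame)`.
#' @export
forward_kinematics <- function(model, pose = numeric(0)) {
  states <- list(ground = list(R = diag(3), p = c(0, 0, 0)))
  for (j in model$joints) {
    par <- states[[j$parent]]
    ang <- joint_zyx_angles(j, pose)
    Rj <- j$triad %*% rot_zyx(ang[["z"]], ang[["y"]], ang[["x"]]) %*% t(j$triad)
    tr <- joint_translation(j, pose)
    p <- par$p + par$R %*% (j$origin + tr)
    states[[j$child]] <- list(R = par$R %*% Rj, p = as.numeric(p))
  }
  states[names(model$segments)]
}

# World position of a local point on a segment, given an FK state list.
fk_point <- function(states, seg, point) {
  s <- states[[seg]]
  as.numeric(s$p + s$R %*% point)
}

#' World position of a named landmark
#'
#' @param model a [msk_model()]; `pose` as in [forward_kinematics()].
#' @param segment segment name; `landmark` landmark name on that segment.
#' @param pose pose vector.
#' @return length-3 position in the ground frame (m).
#' @export
landmark_position <- function(model, pose, segment, landmark) {
  lm <- model$segments[[segment]]$landmarks[[landmark]]
  if (is.null(lm)) stop("no landmark '", landmark, "' on segment '", segment, "'")
  fk_point(forward_kinematics(model, pose), segment, lm)
}

# World direction of the rotation axis of coordinate `coord` at `pose`, and
# the joint it belongs to. Used for projecting joint moments onto dof axes.
coord_axis_world <- function(model, states, pose, coord) {
  for (j in model$joints) {
    idx <- match(coord, j$dofs$name)
    if (!is.na(idx)) {
      par_R <- if (j$parent == "ground") diag(3) else states[[j$parent]]$R
      d <- j$dofs[idx, ]
      ang <- joint_zyx_angles(j, pose)
      if (d$axis %in% c("tx", "ty", "tz")) {
        ax <- match(substring(d$axis, 2L), c("x", "y", "z"))
        return(list(joint = j, axis = as.numeric(par_R %*% j$triad[, ax]) * d$sign,
                    translational = TRUE))
      }
      # intrinsic z-y-x: the y axis is rotated by Rz, the x axis by Rz Ry
      Rpre <- switch(d$axis,
                     z = diag(3),
                     y = rot_z(ang[["z"]]),
                     x = rot_z(ang[["z"]]) %*% rot_y(ang[["y"]]))
      e <- j$triad %*% Rpre %*% diag(3)[, match(d$axis, c("x", "y", "z"))]
      return(list(joint = j, axis = as.numeric(par_R %*% e) * d$sign,
                  translational = FALSE))
    }
  }
  stop("unknown coordinate '", coord, "'")
}

# Joint centre position in the ground frame at the current FK state. The
# child frame origin coincides with the joint centre by construction.
joint_center_world <- function(model, states, joint) {
  states[[model$joints[[joint]]$child]]$p
}
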