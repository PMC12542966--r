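# Femoral midshaft load analysis: cross-sectional geometry from polygon
# outlines or pixel masks, joint reaction recursion with muscle point forces,
# beam-theory stresses (bending, axial, torsion), the unsymmetric-bending
# generalization, section-modulus regression, safety factors and
# strain-to-stress conversion.
#
# Section-plane axis convention: coordinates (y, z) are the midshaft
# mediolateral (y) and dorsoventral (z) axes. I_y = integral of z^2 dA is the
# second moment about the y axis; the extreme-fibre distance paired with it
# ("y" in the stress formulas) is the mean of the dorsal-most and
# ventral-most distances from the y axis, i.e. of |z|.

# Green's-theorem integrals over a simple closed polygon (columns y, z).
# Returns raw moments about the input origin.
polygon_moments <- function(p) {
  p <- as.matrix(p)
  if (all(p[1L, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
  y <- p[, 1L]; z <- p[, 2L]
  y2 <- c(y[-1L], y[1L]); z2 <- c(z[-1L], z[1L])
  cr <- y * z2 - y2 * z
  A <- sum(cr) / 2
  Sy <- sum((y + y2) * cr) / 6       # integral y dA
  Sz <- sum((z + z2) * cr) / 6       # integral z dA
  Iyy <- sum((y^2 + y * y2 + y2^2) * cr) / 12     # integral y^2 dA
  Izz <- sum((z^2 + z * z2 + z2^2) * cr) / 12     # integral z^2 dA
  Iyz <- sum((y * z2 + 2 * y * z + 2 * y2 * z2 + y2 * z) * cr) / 24
  list(A = A, Sy = Sy, Sz = Sz, Iyy = Iyy, Izz = Izz, Iyz = Iyz)
}

# Self-intersection test for a closed polygon (non-adjacent edge pairs).
# The exhaustive O(n^2) scan is run up to a vertex budget; denser outlines
# (digitized sections) are checked on a decimated copy.
polygon_simple <- function(p, max_vertices = 400L) {
  p <- as.matrix(p)
  if (all(p[1L, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
  if (nrow(p) > max_vertices)
    p <- p[unique(round(seq(1L, nrow(p), length.out = max_vertices))), ,
           drop = FALSE]
  n <- nrow(p)
  seg <- function(i) rbind(p[i, ], p[if (i == n) 1L else i + 1L, ])
  inter <- function(a, b) {
    d1 <- a[2L, ] - a[1L, ]; d2 <- b[2L, ] - b[1L, ]
    den <- d1[1L] * d2[2L] - d1[2L] * d2[1L]
    if (abs(den) < 1e-15) return(FALSE)
    w <- b[1L, ] - a[1L, ]
    t <- (w[1L] * d2[2L] - w[2L] * d2[1L]) / den
    u <- (w[1L] * d1[2L] - w[2L] * d1[1L]) / den
    t > 1e-12 && t < 1 - 1e-12 && u > 1e-12 && u < 1 - 1e-12
  }
  for (i in seq_len(n - 2L))
    for (j in seq(i + 2L, n))
      if (!(i == 1L && j == n) && inter(seg(i), seg(j))) return(FALSE)
  TRUE
}

#' Cross-sectional geometric properties
#'
#' Computes area, second moments of area, product of inertia, polar moment,
#' extreme-fibre distances and section moduli of a midshaft cross-section,
#' all about the section centroid. Input is either a simple closed polygon
#' (n x 2 matrix of y, z coordinates in metres, optionally with an inner
#' void outline) or a logical pixel mask with a pixel size.
#'
#' The extreme-fibre distance `y` is the mean of the dorsal-most and
#' ventral-most perpendicular distances to the (mediolateral) y axis, and
#' `z` the mean of the medial-most and lateral-most distances to the
#' (dorsoventral) z axis, matching their use in the bending-stress formulas.
#' The polar moment is `J = I_y + I_z`.
#'
#' @param outline n x 2 polygon (m) or a logical matrix mask.
#' @param inner optional inner (endosteal) void polygon.
#' @param pixel_size pixel edge length (m), required for mask input.
#' @return an object of class `cross_section` with fields `A`, `Iy`, `Iz`,
#'   `Iyz`, `J`, `y`, `z`, `Zy`, `Zz`, `Zp` (polar section modulus
#'   `2J/(y+z)`), `centroid`, and the centred source polygon(s).
#' @export
section_properties <- function(outline, inner = NULL, pixel_size = NULL) {
  if (is.matrix(outline) && is.logical(outline)) {
    if (is.null(pixel_size)) stop("pixel_size required for mask input")
    idx <- which(outline, arr.ind = TRUE)
    y <- (idx[, 1L] - 0.5) * pixel_size
    z <- (idx[, 2L] - 0.5) * pixel_size
    dA <- pixel_size^2
    A <- length(y) * dA
    cy <- mean(y); cz <- mean(z)
    y <- y - cy; z <- z - cz
    # per-pixel second moments include the pixel's own inertia
    pix <- pixel_size^4 / 12
    Iy <- sum(z^2) * dA + length(y) * pix
    Iz <- sum(y^2) * dA + length(y) * pix
    Iyz <- sum(y * z) * dA
    ybar <- (max(z) - min(z)) / 2 + pixel_size / 2
    zbar <- (max(y) - min(y)) / 2 + pixel_size / 2
    poly <- NULL
  } else {
    outline <- as.matrix(outline)
    if (!polygon_simple(outline)) stop("invalid geometry: outline self-intersects")
    if (!is.null(inner) && !polygon_simple(as.matrix(inner)))
      stop("invalid geometry: inner outline self-intersects")
    mo <- polygon_moments(outline)
    sgn <- if (mo$A < 0) -1 else 1   # accept either orientation
    mo <- lapply(mo, `*`, sgn)
    if (!is.null(inner)) {
      mi <- polygon_moments(as.matrix(inner))
      sgn_i <- if (mi$A < 0) -1 else 1
      mi <- lapply(mi, function(v) v * sgn_i)
      mo <- Map(`-`, mo, mi)
    }
    A <- mo$A
    if (A <= 0) stop("invalid geometry: non-positive area")
    cy <- mo$Sy / A; cz <- mo$Sz / A
    Iy <- mo$Izz - A * cz^2          # about centroidal y axis: integral z^2
    Iz <- mo$Iyy - A * cy^2
    Iyz <- mo$Iyz - A * cy * cz
    poly <- sweep(outline, 2L, c(cy, cz))
    zc <- poly[, 2L]; yc <- poly[, 1L]
    ybar <- (max(zc) + abs(min(zc))) / 2
    zbar <- (max(yc) + abs(min(yc))) / 2
  }
  J <- Iy + Iz
  structure(list(A = A, Iy = Iy, Iz = Iz, Iyz = Iyz, J = J,
                 y = ybar, z = zbar,
                 Zy = Iy / ybar, Zz = Iz / zbar, Zp = 2 * J / (ybar + zbar),
                 centroid = c(cy, cz), polygon = poly,
                 inner = if (!is.null(inner) && !is.null(poly))
                   sweep(as.matrix(inner), 2L, c(cy, cz)) else NULL),
            class = "cross_section")
}

#' @export
print.cross_section <- function(x, ...) {
  cat("Cross-section: A = ", format(x$A), " m^2, Iy = ", format(x$Iy),
      ", Iz = ", format(x$Iz), ", Iyz = ", format(x$Iyz), ", J = ",
      format(x$J), " m^4\n", sep = "")
  invisible(x)
}

#' Beam-theory stresses at the femoral midshaft
#'
#' For section loads expressed in the midshaft frame (x axial-distal, y
#' mediolateral, z dorsoventral):
#' \deqn{\sigma_{bend} = \sqrt{(M_y y / I_y)^2 + (M_z z / I_z)^2},\quad
#'   \sigma_{ax} = F_x / A,}
#' \deqn{\sigma_{tens} = \sigma_{bend} + \sigma_{ax},\quad
#'   \sigma_{comp} = -\sigma_{bend} + \sigma_{ax},\quad
#'   \sigma_{tor} = M_x (y + z) / (2 J),}
#' and the neutral-axis angle \eqn{\varphi_{na} = \mathrm{atan}(M_z / M_y)}
#' (zero when the neutral axis lies along the mediolateral y axis; positive,
#' below \eqn{\pi/2}, for a counterclockwise rotation in distal view). The
#' formulas assume bone material distributed symmetrically about the y and z
#' axes; see [asymmetric_bending_stress()] for the product-of-inertia
#' generalization. Tension is positive.
#'
#' @param Fx axial force (N); `Mx`, `My`, `Mz` section moments (N m). May be
#'   vectors (one element per timestep).
#' @param section a [section_properties()] object.
#' @return data frame with columns `sigma_bend`, `sigma_ax`, `sigma_tens`,
#'   `sigma_comp`, `sigma_tor` (Pa) and `phi_na` (rad).
#' @export
bone_stresses <- function(Fx, Mx, My, Mz, section) {
  if (section$A <= 0 || section$Iy <= 0 || section$Iz <= 0 || section$J <= 0)
    stop("invalid geometry: zero area or moment of area")
  sb <- sqrt((My * section$y / section$Iy)^2 + (Mz * section$z / section$Iz)^2)
  sa <- Fx / section$A
  data.frame(sigma_bend = sb, sigma_ax = sa,
             sigma_tens = sb + sa, sigma_comp = -sb + sa,
             sigma_tor = Mx * (section$y + section$z) / (2 * section$J),
             phi_na = atan(Mz / My))
}

#' Unsymmetric bending stress at a point of the cross-section
#'
#' Generalized flexure formula including the product of inertia:
#' \deqn{\sigma(y, z) = \frac{(M_y I_z + M_z I_{yz}) z - (M_z I_y + M_y I_{yz}) y}
#'   {I_y I_z - I_{yz}^2},}
#' the moment components following the true moment-vector convention
#' (\eqn{M_y = \int \sigma z\, dA}, \eqn{M_z = -\int \sigma y\, dA}). When
#' `I_yz = 0` it reduces to the per-axis form underlying [bone_stresses()].
#'
#' @param My,Mz bending moments (N m).
#' @param section a [section_properties()] object.
#' @param point length-2 `(y, z)` position in the centred section plane (m).
#' @return bending stress at the point (Pa), tension positive.
#' @export
asymmetric_bending_stress <- function(My, Mz, section, point) {
  D <- section$Iy * section$Iz - section$Iyz^2
  if (D <= 0) stop("invalid geometry: Iy Iz - Iyz^2 must be positive")
  ((My * section$Iz + Mz * section$Iyz) * point[2L] -
      (Mz * section$Iy + My * section$Iyz) * point[1L]) / D
}

#' Midshaft frame of the femur
#'
#' The femoral centroid line is discretized at `n_stations` stations between
#' the hip and knee joint centres (straight line for the idealized models
#' used here); the frame origin is its midpoint. The x axis points from the
#' midshaft station towards the adjacent distal station; the y (mediolateral)
#' axis is the cross product of x with the knee dorsoventral axis, and z
#' completes the right-handed triad (dorsoventral).
#'
#' @param model a [msk_model()] whose knee joint triad's y column is the
#'   knee dorsoventral axis.
#' @param n_stations number of centroid-line stations.
#' @return list with `origin`, `x`, `y`, `z` (thigh-local coordinates) and
#'   `axial_fraction` (origin position along the hip-knee line).
#' @export
midshaft_frame <- function(model, n_stations = 101L) {
  hip <- c(0, 0, 0)                          # thigh frame origin = hip centre
  knee <- model$joints[["knee"]]$origin      # knee centre in thigh frame
  stations <- seq(0, 1, length.out = n_stations)
  mid_i <- (n_stations + 1L) %/% 2L
  origin <- hip + stations[mid_i] * (knee - hip)
  nxt <- hip + stations[mid_i + 1L] * (knee - hip)
  x <- unit3(nxt - origin)
  knee_dv <- model$joints[["knee"]]$triad[, 2L]   # knee y = dorsoventral
  y <- unit3(cross3(x, knee_dv))
  z <- cross3(x, y)
  list(origin = origin, x = x, y = y, z = z,
       axial_fraction = stations[mid_i])
}

# World-frame muscle point forces for one actuator at one FK state:
# at each attachment/via point the tension pulls towards the neighbouring
# path point(s). Returns list of list(segment, point(world), force(world)).
muscle_point_forces <- function(model, states, act, tension) {
  if (!is.null(act$wrap))
    stop("joint reaction analysis does not support wrap primitives; ",
         "use via points for actuator '", act$name, "'")
  pts <- lapply(act$path, function(p) fk_point(states, p$segment, p$point))
  n <- length(pts)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    f <- c(0, 0, 0)
    if (i > 1L) f <- f + unit3(pts[[i - 1L]] - pts[[i]])
    if (i < n) f <- f + unit3(pts[[i + 1L]] - pts[[i]])
    out[[i]] <- list(segment = act$path[[i]]$segment, point = pts[[i]],
                     force = f * tension)
  }
  out
}

#' Joint reaction analysis
#'
#' Newton-Euler balance per segment from the foot upward, with muscle forces
#' applied along their path lines of action at attachment and via points, the
#' ground reaction force at the CoP, and gravitational plus inertial segment
#' loads (`quasistatic` zeroes the inertial terms). Returns, per joint, the
#' reaction force and moment exerted by the parent segment on the child, and
#' the internal loads at the femoral midshaft expressed in the midshaft
#' frame.
#'
#' The midshaft loads come from the free body distal to the midshaft
#' section plane (distal half-thigh, shank, foot): the knee reaction,
#' gravitational and inertial loads of the distal femoral segment, muscle
#' point forces on it, and the tension of every muscle path segment crossing
#' the section plane, applied at its crossing point. Loads are reported as
#' the action of the distal part on the proximal face (axial tension
#' positive along +x distal).
#'
#' @param model a [msk_model()].
#' @param solution a `muscle_solution` from [solve_trial()].
#' @param trial the corresponding [gait_trial()] (CoP attached).
#' @param frame a [midshaft_frame()]; computed from the model when `NULL`.
#' @param quasistatic logical; drop inertial terms.
#' @return an object of class `joint_reaction` with `joints` (named list of
#'   `force`/`moment` n x 3 matrices, ground frame) and `midshaft` (n x 4
#'   matrix with columns `Fx`, `Mx`, `My`, `Mz` in the midshaft frame).
#' @export
joint_reaction <- function(model, solution, trial, frame = NULL,
                           quasistatic = FALSE) {
  if (is.null(frame)) frame <- midshaft_frame(model)
  if (is.null(frame$origin)) stop("midshaft frame is not configured")
  if (is.null(trial$cop)) stop("trial has no CoP; run attach_cop() first")
  poses <- trial_poses(model, trial)
  n <- length(trial$time)
  kin <- segment_kinematics(model, poses, trial$time, quasistatic)
  gvec <- c(0, 0, -model$gravity)
  jn <- names(model$joints)
  joints <- lapply(jn, function(j) list(force = matrix(0, n, 3L),
                                        moment = matrix(0, n, 3L)))
  names(joints) <- jn
  mid <- matrix(0, n, 4L, dimnames = list(NULL, c("Fx", "Mx", "My", "Mz")))
  thigh <- model$segments$thigh
  knee_o <- model$joints[["knee"]]$origin
  # distal half-thigh mass properties (uniform density along the bone line)
  ax_f <- frame$axial_fraction
  m_dist <- thigh$mass * (1 - ax_f)
  com_dist_local <- frame$origin + (knee_o - frame$origin) / 2
  for (i in seq_len(n)) {
    states <- kin$states[[i]]
    ext <- list(foot = list(list(point = trial$cop[i, ],
                                 force = trial$grf[i, ])))
    mus <- list()
    for (k in seq_along(model$actuators)) {
      mus[[k]] <- muscle_point_forces(model, states, model$actuators[[k]],
                                      solution$forces[i, k])
      for (pf in mus[[k]]) ext[[pf$segment]] <- c(ext[[pf$segment]], list(pf))
    }
    ne <- newton_euler_frame(model, kin, i, ext, gvec)
    for (j in jn) {
      child <- model$joints[[j]]$child
      joints[[j]]$force[i, ] <- ne$force[[child]]
      joints[[j]]$moment[i, ] <- ne$moment[[child]]
    }
    # --- midshaft section loads ---
    Rt <- states$thigh$R
    o_w <- fk_point(states, "thigh", frame$origin)
    x_w <- as.numeric(Rt %*% frame$x)
    y_w <- as.numeric(Rt %*% frame$y)
    z_w <- as.numeric(Rt %*% frame$z)
    # inertial/gravity loads of the distal free body (foot, shank, distal
    # thigh), GRF, muscle point forces distal of the plane, crossing tensions
    F_sum <- c(0, 0, 0); M_sum <- c(0, 0, 0)
    for (s in c("foot", "shank")) {
      m <- model$segments[[s]]$mass
      st <- states[[s]]
      Iw <- st$R %*% model$segments[[s]]$inertia %*% t(st$R)
      Fs <- m * (kin[[s]]$acc[i, ] - gvec)
      Ms <- as.numeric(Iw %*% kin[[s]]$alpha[i, ]) +
        cross3(kin[[s]]$omega[i, ], as.numeric(Iw %*% kin[[s]]$omega[i, ]))
      F_sum <- F_sum + Fs
      M_sum <- M_sum + Ms + cross3(kin[[s]]$com[i, ] - o_w, Fs)
    }
    # distal half-thigh (translational inertia from its own COM kinematics;
    # rotational inertia of the half treated with the half-rod tensor)
    com_d_w <- fk_point(states, "thigh", com_dist_local)
    acc_d <- if (quasistatic) c(0, 0, 0) else
      kin$thigh$acc[i, ] +
      cross3(kin$thigh$alpha[i, ], com_d_w - kin$thigh$com[i, ]) +
      cross3(kin$thigh$omega[i, ],
             cross3(kin$thigh$omega[i, ], com_d_w - kin$thigh$com[i, ]))
    Fd <- m_dist * (acc_d - gvec)
    Iw_d <- states$thigh$R %*% (thigh$inertia * (1 - ax_f)^3) %*%
      t(states$thigh$R)
    Md <- as.numeric(Iw_d %*% kin$thigh$alpha[i, ]) +
      cross3(kin$thigh$omega[i, ], as.numeric(Iw_d %*% kin$thigh$omega[i, ]))
    F_sum <- F_sum + Fd
    M_sum <- M_sum + Md + cross3(com_d_w - o_w, Fd)
    # GRF
    F_sum <- F_sum - trial$grf[i, ]
    M_sum <- M_sum - cross3(trial$cop[i, ] - o_w, trial$grf[i, ])
    # Muscle loads crossing the section plane. The free body contains all
    # material distal of the plane, so attachment and via-point forces of
    # muscles inside it are internal; the only muscle loads entering the
    # balance are the tensions of path segments that pierce the plane,
    # applied at the crossing point and pulling the distal free body towards
    # the proximal side. This covers both muscles attaching to and muscles
    # crossing the distal femoral segment.
    for (k in seq_along(model$actuators)) {
      tension <- solution$forces[i, k]
      pts <- lapply(mus[[k]], `[[`, "point")
      xi <- vapply(pts, function(p) sum((p - o_w) * x_w), numeric(1L))
      for (e in seq_len(length(pts) - 1L)) {
        if (xi[e] * xi[e + 1L] < 0) {
          tfrac <- xi[e] / (xi[e] - xi[e + 1L])
          xc <- pts[[e]] + tfrac * (pts[[e + 1L]] - pts[[e]])
          u <- unit3(if (xi[e] < 0) pts[[e]] - xc else pts[[e + 1L]] - xc)
          F_sum <- F_sum - tension * u
          M_sum <- M_sum - cross3(xc - o_w, tension * u)
        }
      }
    }
    # F_sum now holds (inertial content) - (applied loads), i.e. the load the
    # proximal part must transmit to the distal free body through the bone.
    # Section loads are reported as the action of the distal part on the
    # proximal face, so tension (distal part pulled away along +x) is
    # positive.
    F_dop <- -F_sum
    M_dop <- -M_sum
    mid[i, ] <- c(sum(F_dop * x_w), sum(M_dop * x_w),
                  sum(M_dop * y_w), sum(M_dop * z_w))
  }
  structure(list(joints = joints, midshaft = mid, frame = frame,
                 time = trial$time),
            class = "joint_reaction")
}

#' Stress trace at the femoral midshaft over a trial
#'
#' Applies [bone_stresses()] to the midshaft loads of a [joint_reaction()]
#' result.
#'
#' @param reaction a `joint_reaction` object.
#' @param section a [section_properties()] object.
#' @return an object of class `stress_trace`: the per-timestep stress data
#'   frame plus `peak` (named vector of peak values over stance: maximum
#'   `sigma_tens`, minimum `sigma_comp`, maximum `|sigma_tor|` and
#'   `sigma_bend`).
#' @export
stress_trace <- function(reaction, section) {
  m <- reaction$midshaft
  st <- bone_stresses(m[, "Fx"], m[, "Mx"], m[, "My"], m[, "Mz"], section)
  peak <- c(sigma_tens = max(st$sigma_tens),
            sigma_comp = min(st$sigma_comp),
            sigma_tor = max(abs(st$sigma_tor)),
            sigma_bend = max(st$sigma_bend))
  structure(list(time = reaction$time, stresses = st, peak = peak,
                 loads = m),
            class = "stress_trace")
}

#' Section-modulus regression on femur length
#'
#' Log-log ordinary least squares of section modulus on femur length,
#' used to predict moduli of individuals lacking scan data.
#'
#' @param lengths femur lengths (m), positive, at least 3.
#' @param moduli section moduli (m^3), positive, same length.
#' @param query femur length(s) at which to predict.
#' @return list with `prediction`, `exponent`, `coefficient`, `r_squared`
#'   and the fitted `lm` object.
#' @export
section_modulus_regression <- function(lengths, moduli, query) {
  if (length(lengths) < 3L) stop("need at least 3 (length, modulus) pairs")
  if (any(lengths <= 0) || any(moduli <= 0) || any(query <= 0))
    stop("lengths, moduli and query must be positive")
  fit <- stats::lm(log(moduli) ~ log(lengths))
  pred <- exp(stats::predict(fit, newdata = data.frame(lengths = query)))
  # exact power-law inputs trigger a harmless perfect-fit warning
  list(prediction = as.numeric(pred),
       exponent = unname(stats::coef(fit)[2L]),
       coefficient = exp(unname(stats::coef(fit)[1L])),
       r_squared = suppressWarnings(summary(fit))$r.squared,
       fit = fit)
}

#' Safety factor against material failure
#'
#' @param peak_stress peak functional stress (Pa), positive.
#' @param material_stress failure (yield or ultimate) stress (Pa).
#' @return `material_stress / peak_stress`.
#' @export
safety_factor <- function(peak_stress, material_stress) {
  if (any(peak_stress <= 0)) stop("peak stress must be positive")
  material_stress / peak_stress
}

#' Convert bone strain to stress
#'
#' @param strain dimensionless strain (e.g. `1027e-6` for 1027 microstrain).
#' @param E elastic modulus (Pa), positive.
#' @return stress (Pa).
#' @export
strain_to_stress <- function(strain, E = material_properties()$E) {
  if (any(E <= 0)) stop("elastic modulus must be positive")
  E * strain
}
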