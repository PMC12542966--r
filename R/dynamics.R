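# Inverse kinematics (least-squares marker fit) and inverse dynamics
# (recursive Newton-Euler over the stance limb), producing per-coordinate
# external joint moments.

# Central-difference derivative along rows of a matrix (one-sided at ends).
row_deriv <- function(x, time) {
  n <- nrow(x)
  out <- x * 0
  if (n < 2L) return(out)
  out[1L, ] <- (x[2L, ] - x[1L, ]) / (time[2L] - time[1L])
  out[n, ] <- (x[n, ] - x[n - 1L, ]) / (time[n] - time[n - 1L])
  if (n > 2L) {
    idx <- 2:(n - 1L)
    out[idx, ] <- (x[idx + 1L, ] - x[idx - 1L, ]) /
      (time[idx + 1L] - time[idx - 1L])
  }
  out
}

# Angular velocity (world frame) of a sequence of rotation matrices.
angular_velocity <- function(Rs, time) {
  n <- length(Rs)
  w <- matrix(0, n, 3L)
  skew2vec <- function(S) c(S[3L, 2L] - S[2L, 3L],
                            S[1L, 3L] - S[3L, 1L],
                            S[2L, 1L] - S[1L, 2L]) / 2
  for (i in seq_len(n)) {
    if (i == 1L) {
      dR <- (Rs[[2L]] - Rs[[1L]]) / (time[2L] - time[1L])
      Rt <- Rs[[1L]]
    } else if (i == n) {
      dR <- (Rs[[n]] - Rs[[n - 1L]]) / (time[n] - time[n - 1L])
      Rt <- Rs[[n]]
    } else {
      dR <- (Rs[[i + 1L]] - Rs[[i - 1L]]) / (time[i + 1L] - time[i - 1L])
      Rt <- Rs[[i]]
    }
    w[i, ] <- skew2vec(dR %*% t(Rt))
  }
  w
}

# Per-frame, per-segment kinematic state for a trial: FK transforms, COM
# positions/accelerations, angular velocity/acceleration.
segment_kinematics <- function(model, poses, time, quasistatic = FALSE) {
  n <- nrow(poses)
  segs <- names(model$segments)
  states <- vector("list", n)
  for (i in seq_len(n)) states[[i]] <- forward_kinematics(model, poses[i, ])
  kin <- list(states = states)
  for (s in segs) {
    Rs <- lapply(states, function(st) st[[s]]$R)
    com <- t(vapply(seq_len(n), function(i)
      fk_point(states[[i]], s, model$segments[[s]]$com), numeric(3L)))
    if (quasistatic || n < 3L) {
      acc <- com * 0
      w <- matrix(0, n, 3L)
      al <- matrix(0, n, 3L)
    } else {
      acc <- row_deriv(row_deriv(com, time), time)
      w <- angular_velocity(Rs, time)
      al <- row_deriv(w, time)
    }
    kin[[s]] <- list(R = Rs, com = com, acc = acc, omega = w, alpha = al)
  }
  kin
}

# Children of each segment in the chain (named list).
segment_children <- function(model) {
  ch <- stats::setNames(vector("list", length(model$segments)),
                        names(model$segments))
  for (j in model$joints)
    if (j$parent != "ground")
      ch[[j$parent]] <- c(ch[[j$parent]], j$child)
  ch
}

# Joint whose child is the given segment.
parent_joint <- function(model, seg) {
  for (j in model$joints) if (j$child == seg) return(j)
  stop("segment '", seg, "' has no parent joint")
}

# One frame of the Newton-Euler recursion. `ext` is a named list (by
# segment) of lists of list(point =, force =) external loads (e.g. the GRF
# on the foot, muscle point forces for joint reaction analysis).
# Returns, per segment, the force and moment applied by the parent at the
# proximal joint centre (ground frame).
newton_euler_frame <- function(model, kin, i, ext = list(), gvec) {
  segs <- names(model$segments)
  children <- segment_children(model)
  Jf <- list(); Jm <- list()
  for (s in rev(segs)) {  # chain order: distal segments come last
    m <- model$segments[[s]]$mass
    st <- kin$states[[i]][[s]]
    com <- kin[[s]]$com[i, ]
    acc <- kin[[s]]$acc[i, ]
    w <- kin[[s]]$omega[i, ]
    al <- kin[[s]]$alpha[i, ]
    Iw <- st$R %*% model$segments[[s]]$inertia %*% t(st$R)
    Fnet <- m * (acc - gvec)
    Mnet <- as.numeric(Iw %*% al) + cross3(w, as.numeric(Iw %*% w))
    jpos <- joint_center_world(model, kin$states[[i]], parent_joint(model, s)$name)
    f <- Fnet
    mm <- Mnet + cross3(com - jpos, Fnet)
    for (e in ext[[s]] %||% list()) {
      f <- f - e$force
      mm <- mm - cross3(e$point - jpos, e$force)
    }
    for (c in children[[s]] %||% character(0)) {
      cj <- joint_center_world(model, kin$states[[i]], parent_joint(model, c)$name)
      f <- f + Jf[[c]]
      mm <- mm + Jm[[c]] + cross3(cj - jpos, Jf[[c]])
    }
    Jf[[s]] <- f
    Jm[[s]] <- mm
  }
  list(force = Jf, moment = Jm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Inverse dynamics over a stance trial
#'
#' Recursive Newton-Euler over the limb chain (foot upward), including
#' gravitational and inertial terms, with the measured ground reaction force
#' applied at the centre of pressure. Velocities and accelerations come from
#' central differences of the (filtered) coordinate trajectories; the
#' `quasistatic` flag zeroes all accelerations and angular velocities.
#'
#' The result holds, per enabled coordinate, the generalized external joint
#' moment (N m; N for the translational residual coordinates) that muscles
#' plus reserve/residual actuators must balance, together with its
#' mass^(-4/3)-normalized counterpart and the instant of peak magnitude.
#'
#' @param model a [msk_model()].
#' @param trial a [gait_trial()] with `cop` attached (see [attach_cop()]).
#' @param quasistatic logical; drop inertial terms.
#' @return an object of class `ss_moment_trace` with elements `time`,
#'   `moments` (n x n_coord matrix), `normalized`, `peak_index` and
#'   `peak_moment` (named per coordinate).
#' @export
inverse_dynamics <- function(model, trial, quasistatic = FALSE) {
  if (is.null(trial$cop)) stop("trial has no CoP; run attach_cop() first")
  poses <- trial_poses(model, trial)
  if (nrow(poses) != length(trial$time))
    stop("time vector mismatch between angles and time")
  n <- length(trial$time)
  kin <- segment_kinematics(model, poses, trial$time, quasistatic)
  gvec <- c(0, 0, -model$gravity)
  coords <- model_coords(model)
  mom <- matrix(0, n, length(coords), dimnames = list(NULL, coords))
  for (i in seq_len(n)) {
    ext <- list(foot = list(list(point = trial$cop[i, ],
                                 force = trial$grf[i, ])))
    ne <- newton_euler_frame(model, kin, i, ext, gvec)
    for (cn in coords) {
      ca <- coord_axis_world(model, kin$states[[i]], poses[i, ], cn)
      child <- ca$joint$child
      mom[i, cn] <- if (ca$translational)
        sum(ne$force[[child]] * ca$axis)
      else
        sum(ne$moment[[child]] * ca$axis)
    }
  }
  peak_idx <- apply(abs(mom), 2L, which.max)
  structure(list(time = trial$time, moments = mom,
                 normalized = normalize_moment(mom, trial$body_mass),
                 peak_index = peak_idx,
                 peak_moment = stats::setNames(
                   mom[cbind(peak_idx, seq_along(coords))], coords)),
            class = "ss_moment_trace")
}

#' Inverse kinematics by per-frame least squares
#'
#' Fits the model's enabled generalized coordinates to world marker
#' trajectories by minimizing the summed squared distance between measured
#' and model marker positions, frame by frame (warm-started from the
#' previous frame). Body roll is structurally locked (the ground-body joint
#' carries no roll coordinate) and the knee and ankle are restricted to
#' extension-flexion by construction.
#'
#' @param model a [msk_model()].
#' @param markers named list; each element an n x 3 world trajectory with
#'   attributes `segment` and `point` giving the model attachment.
#' @param init optional initial pose (radians/metres).
#' @param max_iter maximum optimizer iterations per frame.
#' @return list with `poses` (n x n_coord, radians/metres), `angles`
#'   (degrees for rotations), `residual_rms` (m, per frame) and `flagged`
#'   (frames interpolated after non-convergence).
#' @export
inverse_kinematics <- function(model, markers, init = NULL, max_iter = 200) {
  coords <- model_coords(model)
  n <- nrow(markers[[1L]])
  if (3L * length(markers) < length(coords))
    stop("need at least as many marker coordinates as free dofs")
  segs <- vapply(markers, function(m) attr(m, "segment"), character(1L))
  pts <- lapply(markers, function(m) attr(m, "point"))
  obj <- function(par, i) {
    pose <- stats::setNames(par, coords)
    st <- forward_kinematics(model, pose)
    s <- 0
    for (k in seq_along(markers)) {
      d <- fk_point(st, segs[k], pts[[k]]) - markers[[k]][i, ]
      s <- s + sum(d * d)
    }
    s
  }
  poses <- matrix(0, n, length(coords), dimnames = list(NULL, coords))
  rms <- numeric(n)
  flagged <- integer(0)
  par <- if (is.null(init)) rep(0, length(coords)) else
    vapply(coords, function(cn) init[[cn]] %||% 0, numeric(1L))
  for (i in seq_len(n)) {
    fit <- stats::optim(par, obj, i = i, method = "BFGS",
                        control = list(maxit = max_iter, reltol = 1e-12))
    if (fit$convergence != 0) {
      fit2 <- stats::optim(fit$par, obj, i = i, method = "BFGS",
                           control = list(maxit = max_iter, reltol = 1e-12))
      if (fit2$value <= fit$value) fit <- fit2
      if (fit$convergence != 0) flagged <- c(flagged, i)
    }
    par <- fit$par
    poses[i, ] <- par
    rms[i] <- sqrt(fit$value / (3 * length(markers)))
  }
  good <- setdiff(seq_len(n), flagged)
  if (length(flagged) && length(good) >= 2L) {
    warning("inverse kinematics did not converge at frame(s) ",
            paste(flagged, collapse = ", "), "; interpolated from neighbors")
    for (cn in coords)
      poses[flagged, cn] <- stats::approx(good, poses[good, cn], xout = flagged,
                                          rule = 2)$y
  } else if (length(flagged)) {
    warning("inverse kinematics did not fully converge at frame(s) ",
            paste(flagged, collapse = ", "), "; estimates kept")
    flagged <- integer(0)
  }
  trans <- translational_coords(model)
  angles <- poses
  rot <- setdiff(coords, trans)
  angles[, rot] <- rad2deg(angles[, rot])
  list(poses = poses, angles = angles, residual_rms = rms, flagged = flagged)
}
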