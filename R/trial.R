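# Stance-phase gait trial container and preprocessing: zero-phase low-pass
# filtering, the centre-of-pressure model, and moment normalization.

#' Construct a stance-phase gait trial
#'
#' @param time strictly increasing time vector (s), uniform sampling assumed
#'   by the filtering and derivative steps.
#' @param angles matrix or data frame (one row per sample) of generalized
#'   coordinates: rotational coordinates in degrees, translational body
#'   coordinates (`body_tx` etc.) in metres. Column names must match model
#'   coordinate names.
#' @param grf ground reaction force on the animal, ground frame (N), n x 3.
#' @param cop centre-of-pressure trajectory (m), n x 3, or `NULL` to be
#'   filled by [cop_trajectory()].
#' @param body_mass body mass (kg).
#' @param duty_factor stance duration over stride duration, in `(0, 1]`.
#' @param markers optional named list of n x 3 world marker trajectories,
#'   each with attributes `segment` and `point` (local coordinates).
#' @return an object of class `gait_trial`.
#' @export
gait_trial <- function(time, angles, grf, cop = NULL, body_mass,
                       duty_factor = 0.7, markers = NULL) {
  time <- as.numeric(time)
  if (any(diff(time) <= 0)) stop("time vector must be strictly increasing")
  angles <- as.matrix(angles)
  if (nrow(angles) != length(time)) stop("angles/time length mismatch")
  grf <- as.matrix(grf)
  if (!all(dim(grf) == c(length(time), 3L))) stop("grf must be n x 3")
  if (any(grf[, 3L] < -1e-9))
    stop("GRF vertical component must be non-negative during stance")
  if (duty_factor <= 0 || duty_factor > 1)
    stop("duty factor must lie in (0, 1]")
  if (body_mass <= 0) stop("body mass must be > 0")
  if (!is.null(cop)) {
    cop <- as.matrix(cop)
    if (!all(dim(cop) == c(length(time), 3L))) stop("cop must be n x 3")
  }
  structure(list(time = time, angles = angles, grf = grf, cop = cop,
                 body_mass = body_mass, duty_factor = duty_factor,
                 markers = markers),
            class = "gait_trial")
}

#' @export
print.gait_trial <- function(x, ...) {
  cat("Gait trial: ", length(x$time), " samples over ",
      format(diff(range(x$time))), " s stance, body mass ",
      format(x$body_mass), " kg, duty factor ", format(x$duty_factor),
      "\n", sep = "")
  invisible(x)
}

# Sampling frequency of a uniformly sampled trial.
sampling_rate <- function(time) {
  dt <- diff(time)
  if (diff(range(dt)) > 1e-6 * mean(dt))
    stop("uniform sampling required")
  1 / mean(dt)
}

#' Zero-phase low-pass filter
#'
#' 4th-order Butterworth applied forward and backward (zero phase), with
#' odd-reflection end padding. Works on vectors or column-wise on matrices.
#'
#' @param x numeric vector or matrix (one column per channel).
#' @param fs sampling frequency (Hz).
#' @param cutoff_hz cutoff frequency (Hz), default 5 (the convention used for
#'   stance-phase joint angles here).
#' @return filtered data, same shape as `x`.
#' @export
lowpass <- function(x, fs, cutoff_hz = 5) {
  if (cutoff_hz >= fs / 2)
    stop("cutoff must be below the Nyquist frequency")
  bf <- signal::butter(4, cutoff_hz / (fs / 2), type = "low")
  filt1 <- function(v) {
    n <- length(v)
    mu <- mean(v)           # filter deviations so the DC level is exact
    v <- v - mu
    p <- min(n - 1L, ceiling(6 * fs / cutoff_hz))
    left <- 2 * v[1L] - v[seq(p + 1L, 2L)]
    right <- 2 * v[n] - v[seq(n - 1L, n - p)]
    vp <- c(left, v, right)
    out <- signal::filtfilt(bf, vp)
    out[seq(p + 1L, p + n)] + mu
  }
  if (is.matrix(x)) {
    out <- apply(x, 2L, filt1)
    dimnames(out) <- dimnames(x)
    out
  } else filt1(x)
}

#' Filter the joint angles of a trial
#'
#' @param trial a [gait_trial()].
#' @param cutoff_hz low-pass cutoff (Hz).
#' @return the trial with filtered `angles`.
#' @export
filter_trial <- function(trial, cutoff_hz = 5) {
  fs <- sampling_rate(trial$time)
  trial$angles <- lowpass(trial$angles, fs, cutoff_hz)
  trial
}

#' Centre-of-pressure model
#'
#' During the first half of stance the CoP sits at the ground projection of
#' the metatarsophalangeal (MTP-III) marker (`mode = "default"`) or of the
#' midpoint between the ankle and MTP-III markers (`mode = "ankleward"`,
#' the sensitivity variant). Over the second half it shifts linearly towards
#' the toe tip, reaching it at the end of stance.
#'
#' @param ankle,mtp,toe ground-frame landmark positions: length-3 vectors or
#'   n x 3 matrices.
#' @param t stance fraction(s) in `[0, 1]`.
#' @param mode `"default"` or `"ankleward"`.
#' @return CoP position(s) on the ground plane: n x 3 matrix.
#' @export
cop_trajectory <- function(ankle, mtp, toe, t, mode = c("default", "ankleward")) {
  mode <- match.arg(mode)
  as_mat <- function(p) if (is.matrix(p)) p else matrix(p, length(t), 3L,
                                                        byrow = TRUE)
  n <- length(t)
  ankle <- as_mat(ankle); mtp <- as_mat(mtp); toe <- as_mat(toe)
  proj <- function(p) cbind(p[, 1:2, drop = FALSE], 0)
  a <- proj(ankle); m <- proj(mtp); tt <- proj(toe)
  if (min(sqrt(rowSums((m - tt)^2))) < 1e-9 ||
      min(sqrt(rowSums((a - m)^2))) < 1e-9)
    stop("degenerate (coincident) foot landmarks")
  p0 <- if (mode == "default") m else (a + m) / 2
  w <- pmax(0, (t - 0.5) / 0.5)
  p0 * (1 - w) + tt * w
}

#' Attach the modelled CoP to a trial
#'
#' Runs forward kinematics on the trial's (already filtered) joint angles to
#' place the foot landmarks (`ankle`, `mtp`, `toe`), then applies
#' [cop_trajectory()].
#'
#' @param model a [msk_model()]; the foot segment must carry `ankle`, `mtp`
#'   and `toe` landmarks.
#' @param trial a [gait_trial()].
#' @param mode CoP mode, see [cop_trajectory()].
#' @return the trial with `cop` filled in.
#' @export
attach_cop <- function(model, trial, mode = "default") {
  poses <- trial_poses(model, trial)
  n <- nrow(poses)
  lms <- c("ankle", "mtp", "toe")
  pts <- lapply(lms, function(l) matrix(0, n, 3L))
  names(pts) <- lms
  for (i in seq_len(n)) {
    st <- forward_kinematics(model, poses[i, ])
    for (l in lms)
      pts[[l]][i, ] <- fk_point(st, "foot", model$segments$foot$landmarks[[l]])
  }
  tfrac <- (trial$time - trial$time[1L]) /
    (trial$time[length(trial$time)] - trial$time[1L])
  trial$cop <- cop_trajectory(pts$ankle, pts$mtp, pts$toe, tfrac, mode)
  trial
}

#' Normalize a joint moment for body size
#'
#' Divides by mass^(4/3) (units N m kg^-4/3), the geometric expectation for
#' moments under isometry, enabling comparison across body sizes.
#'
#' @param moment joint moment(s) (N m).
#' @param mass body mass (kg), positive.
#' @return normalized moment(s).
#' @export
normalize_moment <- function(moment, mass) {
  if (any(mass <= 0)) stop("mass must be > 0")
  moment / mass^(4 / 3)
}

# Convert the trial's angle table (degrees / metres) into a pose matrix in
# radians / metres, using the model's dof axis metadata to tell rotations
# from translations.
trial_poses <- function(model, trial) {
  coords <- model_coords(model)
  trans <- translational_coords(model)
  have <- intersect(coords, colnames(trial$angles))
  poses <- matrix(0, nrow(trial$angles), length(coords),
                  dimnames = list(NULL, coords))
  for (cn in have) {
    v <- trial$angles[, cn]
    poses[, cn] <- if (cn %in% trans) v else deg2rad(v)
  }
  poses
}

translational_coords <- function(model) {
  unlist(lapply(model$joints, function(j)
    j$dofs$name[j$dofs$axis %in% c("tx", "ty", "tz")]), use.names = FALSE)
}
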