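# Allometric scaling of models and gait trials across body sizes, including
# the reconstruction pathway for the giant extinct alligatoroid preset.

#' Scaling specification
#'
#' @param target_mass target body mass (kg).
#' @param length_factors named numeric vector of per-segment length scale
#'   factors, names `body`, `thigh`, `shank`, `foot`; all positive.
#' @param fmax_exponent allometric exponent `b` for maximal isometric force,
#'   `F_max` scaling as (mass ratio)^b. The default 0.67 corresponds to
#'   isometric scaling of physiological cross-sectional area; 0.7, 0.75 and
#'   0.8 probe progressively stronger positive allometry. Must lie in
#'   `[0.6, 0.9]`.
#' @param scale_grf,scale_time logical flags for trial scaling (ground
#'   reaction force proportional to mass; stance time as mass^(1/6)).
#' @return an object of class `ss_scaling_spec`.
#' @export
scaling_spec <- function(target_mass,
                         length_factors = c(body = 1, thigh = 1, shank = 1,
                                            foot = 1),
                         fmax_exponent = 0.67, scale_grf = TRUE,
                         scale_time = TRUE) {
  if (target_mass <= 0) stop("target mass must be > 0")
  if (any(length_factors <= 0)) stop("length scale factors must be > 0")
  if (fmax_exponent < 0.6 || fmax_exponent > 0.9)
    stop("fmax exponent must lie in [0.6, 0.9]")
  structure(list(target_mass = target_mass,
                 length_factors = length_factors,
                 fmax_exponent = fmax_exponent,
                 scale_grf = scale_grf, scale_time = scale_time),
            class = "ss_scaling_spec")
}

#' F_max ratio under allometric scaling
#'
#' @param mass_ratio ratio of target to base body mass, positive.
#' @param b allometric exponent.
#' @return `mass_ratio^b`.
#' @export
fmax_ratio <- function(mass_ratio, b = 0.67) {
  if (any(mass_ratio <= 0)) stop("mass ratio must be > 0")
  mass_ratio^b
}

#' Scale a musculoskeletal model
#'
#' Segment lengths, landmarks, centres of mass, joint origins and muscle path
#' points scale with their segment's length factor (joint origins with the
#' parent segment's factor). Segment masses scale with the total mass ratio
#' and inertia tensors with mass ratio times length factor squared. Each
#' actuator's optimal fibre length and tendon slack length scale with its
#' primary segment's factor, its belly mass with the mass ratio, and `F_max`
#' with (mass ratio)^b.
#'
#' @param base a [msk_model()].
#' @param spec a [scaling_spec()].
#' @return the scaled [msk_model()].
#' @export
scale_model <- function(base, spec) {
  lf <- spec$length_factors
  missing_f <- setdiff(names(base$segments), names(lf))
  if (length(missing_f))
    stop("missing length scale factor for segment(s): ",
         paste(missing_f, collapse = ", "))
  mr <- spec$target_mass / base$body_mass
  segs <- lapply(base$segments, function(s) {
    k <- lf[[s$name]]
    s$mass <- s$mass * mr
    s$com <- s$com * k
    s$inertia <- s$inertia * mr * k^2
    s$length <- s$length * k
    s$landmarks <- lapply(s$landmarks, function(p) p * k)
    s
  })
  joints <- lapply(base$joints, function(j) {
    kp <- if (j$parent == "ground") 1 else lf[[j$parent]]
    j$origin <- j$origin * kp
    j
  })
  acts <- lapply(base$actuators, function(a) {
    kp <- lf[[a$primary_segment]]
    a$path <- lapply(a$path, function(p) {
      p$point <- p$point * lf[[p$segment]]
      p
    })
    if (!is.null(a$wrap)) {
      kw <- lf[[a$wrap$segment]]
      a$wrap$center <- a$wrap$center * kw
      a$wrap$radius <- a$wrap$radius * kw
    }
    a$l0 <- a$l0 * kp
    a$slack <- a$slack * kp
    a$m_musc <- a$m_musc * mr
    a$fmax <- a$fmax * mr^spec$fmax_exponent
    a
  })
  out <- base
  out$segments <- segs
  out$joints <- joints
  out$actuators <- acts
  out$body_mass <- spec$target_mass
  out
}

#' Vertebral series with missing-value imputation support
#'
#' @param centra ordered dorsal centrum lengths (m); `NA` marks a missing
#'   centrum.
#' @param tl_coef,mass_coef optional power-law coefficients `c(a, b)` for
#'   total length from summed centrum length (`TL = a * sum^b`) and body mass
#'   from total length (`mass = a * TL^b`).
#' @return an object of class `ss_vertebral_series`.
#' @export
vertebral_series <- function(centra, tl_coef = NULL, mass_coef = NULL) {
  if (!any(is.finite(centra)))
    stop("vertebral series must contain at least one observed centrum")
  for (co in list(tl_coef, mass_coef))
    if (!is.null(co) && (length(co) != 2L || any(co <= 0)))
      stop("allometric coefficients must be positive pairs c(a, b)")
  structure(list(centra = as.numeric(centra), tl_coef = tl_coef,
                 mass_coef = mass_coef),
            class = "ss_vertebral_series")
}

#' Impute missing centrum lengths
#'
#' Interior gaps are filled with the mean of the flanking observed centra;
#' terminal gaps take the nearest observed value (a documented convention,
#' since only interior imputation is prescribed by the source procedure).
#'
#' @param series a [vertebral_series()].
#' @return the series with `centra` completed.
#' @export
impute_centra <- function(series) {
  x <- series$centra
  n <- length(x)
  miss <- which(is.na(x))
  for (i in miss) {
    if (i > 1L && i < n && !is.na(x[i - 1L]) && !is.na(x[i + 1L])) {
      x[i] <- (x[i - 1L] + x[i + 1L]) / 2
    }
  }
  # terminal (and any still-unresolved leading/trailing) gaps: nearest observed
  obs <- which(!is.na(x))
  if (any(is.na(x))) {
    for (i in which(is.na(x))) {
      if (i < obs[1L]) x[i] <- x[obs[1L]]
      else if (i > obs[length(obs)]) x[i] <- x[obs[length(obs)]]
      else stop("two consecutive interior centra are missing; cannot impute")
    }
  }
  series$centra <- x
  series
}

# Published outputs of the giant-alligatoroid reconstruction, usable as a
# preset for downstream scaling stages (total length and mass estimated from
# the dorsal vertebral series of specimen TMM43632-1).
.size_presets <- list(
  "deinosuchus-TMM43632-1" = list(total_length = 8.68, mass = 3704.5)
)

#' Body size from a vertebral series
#'
#' Total length follows `TL = a_TL * (sum of centra)^b_TL` and body mass
#' `M = a_M * TL^b_M` with user-supplied coefficients, or a named preset
#' carrying published outputs.
#'
#' @param series a [vertebral_series()] (ignored when `preset` is given).
#' @param preset optional preset name, e.g. `"deinosuchus-TMM43632-1"`.
#' @return list with `total_length` (m) and `mass` (kg).
#' @export
body_size_from_series <- function(series = NULL, preset = NULL) {
  if (!is.null(preset)) {
    ps <- .size_presets[[preset]]
    if (is.null(ps)) stop("unknown size preset '", preset, "'")
    return(ps)
  }
  if (is.null(series$tl_coef) || is.null(series$mass_coef))
    stop("allometric coefficients required when no preset is used")
  s <- impute_centra(series)
  tl <- series$tl_coef[1L] * sum(s$centra)^series$tl_coef[2L]
  mass <- series$mass_coef[1L] * tl^series$mass_coef[2L]
  list(total_length = tl, mass = mass)
}

#' Scale a gait trial by dynamic similarity
#'
#' Ground reaction forces scale proportionally to mass and the time axis
#' stretches as mass^(1/6); joint angles are unchanged.
#'
#' @param base a [gait_trial()].
#' @param mass_ratio ratio of target to base body mass, positive.
#' @return the scaled [gait_trial()].
#' @export
scale_trial <- function(base, mass_ratio) {
  if (mass_ratio <= 0) stop("mass ratio must be > 0")
  out <- base
  out$time <- base$time * mass_ratio^(1 / 6)
  out$grf <- base$grf * mass_ratio
  out$body_mass <- base$body_mass * mass_ratio
  out
}
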