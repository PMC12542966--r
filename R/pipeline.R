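# Cohort orchestration and the summary statistics of the analysis: muscle
# onset/offset timing against a duty-factor-remapped stride, posture
# regressions with significance tiers, per-individual pipeline runs and
# cohort reports (including the F_max-exponent sweep for the giant preset).

#' Muscle onset/offset timing on a stride timeline
#'
#' Thresholds each muscle's stance activation trace at `cutoff` and remaps
#' stance to the fraction `[0, duty_factor)` of the stride, for comparison
#' with electromyographic excitation timings reported on a stride basis.
#' Swing-phase activations are treated as absent (stance is the only
#' simulated phase). A never-active muscle yields an empty interval.
#'
#' @param solution a `muscle_solution`.
#' @param cutoff activation threshold (default 0.05).
#' @param duty_factor stance-to-stride ratio used for the remap (default
#'   0.7).
#' @return data frame with `muscle`, `onset`, `offset` (stride fraction,
#'   `NA` for never-active muscles) and `active` (logical).
#' @export
onset_offset <- function(solution, cutoff = 0.05, duty_factor = 0.7) {
  tfrac <- (solution$time - solution$time[1L]) / diff(range(solution$time))
  res <- lapply(colnames(solution$activations), function(m) {
    a <- solution$activations[, m]
    on <- a >= cutoff
    if (!any(on)) return(data.frame(muscle = m, onset = NA_real_,
                                    offset = NA_real_, active = FALSE))
    i1 <- which(on)[1L]
    i2 <- which(on)[sum(on)]
    # linear interpolation of the threshold crossing
    onset <- if (i1 == 1L) 0 else
      stats::approx(a[(i1 - 1L):i1], tfrac[(i1 - 1L):i1], xout = cutoff)$y
    offset <- if (i2 == length(a)) 1 else
      stats::approx(a[i2:(i2 + 1L)], tfrac[i2:(i2 + 1L)], xout = cutoff)$y
    data.frame(muscle = m, onset = onset * duty_factor,
               offset = offset * duty_factor, active = TRUE)
  })
  out <- do.call(rbind, res)
  attr(out, "duty_factor") <- duty_factor
  out
}

#' Significance tier of a P-value
#'
#' `"significant"` for P < 0.05, `"marginal"` for 0.05 <= P < 0.1, else
#' `"none"`.
#'
#' @param p P-value(s).
#' @return character tier(s).
#' @export
significance_tier <- function(p) {
  ifelse(p < 0.05, "significant", ifelse(p < 0.1, "marginal", "none"))
}

#' Regress a response on mean midstance hip adduction angle
#'
#' Ordinary least squares of a per-individual response (a midstance muscle
#' activation or a bone-stress characteristic) on the mean midstance hip
#' adduction angle, for size-matched individuals. For activation responses,
#' muscles with mean midstance activation below `exclude_below` (default
#' 0.02) are excluded. No mixed-effects structure is used.
#'
#' @param adduction mean midstance hip adduction angles (deg), length >= 3.
#' @param response response values, same length.
#' @param type `"activation"` or `"stress"`; controls the exclusion rule.
#' @param exclude_below activation exclusion threshold.
#' @return an object of class `regression_result`: `slope`, `intercept`,
#'   `p_value`, `tier`, `n`, `excluded` (logical: response dropped by the
#'   activation rule).
#' @export
posture_regression <- function(adduction, response,
                               type = c("stress", "activation"),
                               exclude_below = 0.02) {
  type <- match.arg(type)
  if (length(adduction) != length(response))
    stop("adduction and response lengths differ")
  if (length(adduction) < 3L)
    stop("insufficient data: need at least 3 individuals")
  excluded <- type == "activation" && mean(response) < exclude_below
  if (excluded)
    return(structure(list(slope = NA_real_, intercept = NA_real_,
                          p_value = NA_real_, tier = "excluded",
                          n = length(adduction), excluded = TRUE),
                     class = "regression_result"))
  fit <- stats::lm(response ~ adduction)
  # exactly collinear inputs trigger a harmless perfect-fit warning
  sm <- suppressWarnings(summary(fit))
  p <- if (nrow(sm$coefficients) > 1L && !is.nan(sm$coefficients[2L, 4L]))
    sm$coefficients[2L, 4L] else 0
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 p_value = p, tier = significance_tier(p),
                 n = length(adduction), excluded = FALSE),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat("slope ", format(x$slope, digits = 4), ", P = ",
      format(x$p_value, digits = 3), " (", x$tier, "), n = ", x$n, "\n",
      sep = "")
  invisible(x)
}

#' Run the full inverse-simulation pipeline for one individual
#'
#' Executes filter -> CoP -> inverse dynamics -> static optimization ->
#' joint reaction -> bone stress -> summaries for one model/trial pair.
#'
#' @param model a [msk_model()].
#' @param trial a [gait_trial()].
#' @param section a [section_properties()] cross-section; generated from the
#'   model's thigh length via [generate_cross_section()] when `NULL`.
#' @param cop_mode `"default"` or `"ankleward"`.
#' @param quasistatic logical; drop inertial terms throughout.
#' @param hill a [hill_config()].
#' @param config a [reserve_config()]; derived from the model when `NULL`.
#' @param use_velocity apply the force-velocity factor in the optimization.
#' @return an object of class `individual_run` bundling the moment trace,
#'   muscle solution, joint reactions, stress trace, activation summaries,
#'   reserve ratios per coordinate and the configuration used.
#' @export
run_individual <- function(model, trial, section = NULL,
                           cop_mode = "default", quasistatic = FALSE,
                           hill = hill_config(), config = NULL,
                           use_velocity = TRUE) {
  if (is.null(config)) config <- reserve_config(model$body_mass, model$gravity)
  if (is.null(section)) {
    geom <- generate_cross_section(model$segments$thigh$length,
                                   seed = model$seed %||% 1L)
    section <- section_properties(geom$outer, geom$inner)
  }
  trial <- filter_trial(trial)
  trial <- attach_cop(model, trial, mode = cop_mode)
  moments <- inverse_dynamics(model, trial, quasistatic = quasistatic)
  solution <- solve_trial(model, trial, moments = moments, config = config,
                          hill = hill, use_velocity = use_velocity)
  reaction <- joint_reaction(model, solution, trial,
                             quasistatic = quasistatic)
  stresses <- stress_trace(reaction, section)
  musc_coords <- setdiff(colnames(moments$moments),
                         grep("^body_", colnames(moments$moments),
                              value = TRUE))
  rratio <- vapply(musc_coords, function(cn)
    reserve_ratio(solution, moments, cn), numeric(1L))
  tfrac <- (trial$time - trial$time[1L]) / diff(range(trial$time))
  midsel <- tfrac >= 0.25 & tfrac < 0.75
  structure(list(
    trial = trial, moments = moments, solution = solution,
    reaction = reaction, stresses = stresses, section = section,
    activation_summary = activation_summaries(solution),
    reserve_ratios = rratio,
    mean_midstance_adduction = mean(trial$angles[midsel, "hip_aa"]),
    peak = stresses$peak,
    settings = list(cop_mode = cop_mode, quasistatic = quasistatic,
                    use_velocity = use_velocity)),
    class = "individual_run")
}

#' @export
print.individual_run <- function(x, ...) {
  cat("Pipeline run: peak sigma_tens ",
      format(x$peak[["sigma_tens"]] / 1e6, digits = 3), " MPa, peak |sigma_tor| ",
      format(x$peak[["sigma_tor"]] / 1e6, digits = 3), " MPa\n", sep = "")
  invisible(x)
}

#' Run a synthetic cohort through the pipeline
#'
#' Generates one model and trial per individual in the [cohort_spec()],
#' runs [run_individual()] on each, and assembles cross-individual tables:
#' peak stresses and safety factors (yield and ultimate), reserve ratios per
#' coordinate, midstance activation summaries, and (for size-matched
#' cohorts) posture regressions of peak tensile and torsional stress on
#' mean midstance hip adduction.
#'
#' @param spec a [cohort_spec()].
#' @param material a [material_properties()] (for safety factors).
#' @param ... passed on to [run_individual()].
#' @return an object of class `cohort_report` with `runs`, `table` (one row
#'   per individual), `regressions` (when the cohort is size-matched) and
#'   `spec`.
#' @export
run_cohort <- function(spec, material = material_properties(), ...) {
  ind <- spec$individuals
  runs <- vector("list", nrow(ind))
  names(runs) <- ind$id
  for (i in seq_len(nrow(ind))) {
    model <- generate_model(ind$mass[i], seed = ind$seed[i],
                            fmax_exponent = spec$fmax_exponent)
    trial <- generate_trial(model,
                            abduction_offset = ind$abduction_offset[i],
                            knee_offset = if (is.na(ind$knee_offset[i])) NULL
                                          else ind$knee_offset[i],
                            duty_factor = ind$duty_factor[i],
                            duration_ref = spec$duration_ref,
                            rate = spec$rate,
                            marker_noise = spec$marker_noise,
                            grf_noise = spec$grf_noise,
                            seed = ind$seed[i])
    runs[[i]] <- tryCatch(run_individual(model, trial, ...),
                          error = function(e) e)
  }
  ok <- !vapply(runs, inherits, logical(1L), "error")
  tab <- do.call(rbind, lapply(which(ok), function(i) {
    r <- runs[[i]]
    data.frame(id = ind$id[i], mass = ind$mass[i],
               mean_midstance_adduction = r$mean_midstance_adduction,
               peak_sigma_tens = r$peak[["sigma_tens"]],
               peak_sigma_comp = r$peak[["sigma_comp"]],
               peak_sigma_tor = r$peak[["sigma_tor"]],
               sf_yield = safety_factor(r$peak[["sigma_tens"]],
                                        material$yield_stress),
               sf_ultimate = safety_factor(r$peak[["sigma_tens"]],
                                           material$ultimate_stress),
               rr_hip_ef = r$reserve_ratios[["hip_ef"]],
               rr_hip_aa = r$reserve_ratios[["hip_aa"]],
               rr_knee = r$reserve_ratios[["knee_ef"]],
               rr_ankle = r$reserve_ratios[["ankle_ef"]])
  }))
  regressions <- NULL
  if (sum(ok) >= 3L && diff(range(ind$mass[ok])) < 1e-9 * mean(ind$mass[ok])) {
    regressions <- list(
      sigma_tens = posture_regression(tab$mean_midstance_adduction,
                                      tab$peak_sigma_tens, type = "stress"),
      sigma_tor = posture_regression(tab$mean_midstance_adduction,
                                     tab$peak_sigma_tor, type = "stress"),
      tor_tens_ratio = posture_regression(
        tab$mean_midstance_adduction,
        tab$peak_sigma_tor / tab$peak_sigma_tens, type = "stress"))
  }
  structure(list(runs = runs, table = tab, regressions = regressions,
                 spec = spec, failed = names(runs)[!ok]),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Cohort report: ", nrow(x$table), " individual(s)\n", sep = "")
  print(x$table, digits = 4)
  invisible(x)
}

#' F_max-exponent sweep for a dynamically scaled giant
#'
#' Scales a base model and trial to a target (giant) mass under dynamic
#' similarity, once per F_max exponent, and reports the reserve ratios per
#' coordinate. This probes how strongly muscle capacity must scale with
#' body mass to keep reserve usage at the level seen in the largest extant
#' individuals.
#'
#' @param base_mass base body mass (kg) of the reference model/trial.
#' @param target_mass giant body mass (kg), e.g. the 3704.5 kg preset.
#' @param exponents F_max exponents to sweep.
#' @param seed generator seed.
#' @param ... passed to [run_individual()].
#' @return data frame with one row per exponent: reserve ratios per
#'   coordinate and peak tensile stress.
#' @export
fmax_exponent_sweep <- function(base_mass = .ref_mass, target_mass = 3704.5,
                                exponents = c(0.67, 0.7, 0.75, 0.8),
                                seed = 1L, ...) {
  out <- lapply(exponents, function(b) {
    model <- generate_model(target_mass, seed = seed, fmax_exponent = b)
    trial <- generate_trial(model, seed = seed)
    r <- run_individual(model, trial, ...)
    data.frame(exponent = b,
               rr_hip_ef = r$reserve_ratios[["hip_ef"]],
               rr_hip_aa = r$reserve_ratios[["hip_aa"]],
               rr_knee = r$reserve_ratios[["knee_ef"]],
               rr_ankle = r$reserve_ratios[["ankle_ef"]],
               peak_sigma_tens = r$peak[["sigma_tens"]])
  })
  do.call(rbind, out)
}
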