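# File interfaces: model definition documents (YAML, versioned schema, SI
# units with degree-valued angles), gait trials and cross-section outlines as
# delimited tables, and tidy CSV export of solutions and stress traces.

#' Write a model definition file
#'
#' Serializes a [msk_model()] to a versioned YAML document (SI units; the
#' numeric content round-trips through [read_model()]).
#'
#' @param model a [msk_model()].
#' @param path output file path.
#' @export
write_model <- function(model, path) {
  doc <- list(
    schema = "sprawlsim-model/1",
    body_mass = model$body_mass,
    gravity = model$gravity,
    material = unclass(model$material),
    segments = lapply(unname(model$segments), function(s) list(
      name = s$name, mass = s$mass, com = as.numeric(s$com),
      inertia = as.numeric(s$inertia), length = s$length,
      landmarks = lapply(s$landmarks, as.numeric))),
    joints = lapply(unname(model$joints), function(j) list(
      name = j$name, parent = j$parent, child = j$child,
      origin = as.numeric(j$origin), triad = as.numeric(j$triad),
      dofs = lapply(seq_len(nrow(j$dofs)), function(k) as.list(j$dofs[k, ])))),
    actuators = lapply(unname(model$actuators), function(a) list(
      name = a$name,
      path = lapply(a$path, function(p) list(segment = p$segment,
                                             point = as.numeric(p$point))),
      m_musc = a$m_musc, l0 = a$l0, pennation = a$pennation,
      slack = a$slack, fmax = a$fmax, primary_segment = a$primary_segment,
      group = a$group,
      wrap = if (is.null(a$wrap)) NULL else list(
        segment = a$wrap$segment, center = as.numeric(a$wrap$center),
        axis = as.numeric(a$wrap$axis), radius = a$wrap$radius,
        between = as.integer(a$wrap$between))))
  )
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}

#' Read a model definition file
#'
#' @param path path to a YAML document written by [write_model()].
#' @return a [msk_model()].
#' @export
read_model <- function(path) {
  doc <- yaml::read_yaml(path)
  if (!identical(doc$schema, "sprawlsim-model/1"))
    stop("unsupported model schema: ", doc$schema)
  segs <- lapply(doc$segments, function(s)
    segment(s$name, s$mass, com = unlist(s$com),
            inertia = matrix(unlist(s$inertia), 3L, 3L), length = s$length,
            landmarks = lapply(s$landmarks, unlist)))
  joints <- lapply(doc$joints, function(j)
    jcs(j$name, j$parent, j$child, origin = unlist(j$origin),
        triad = matrix(unlist(j$triad), 3L, 3L),
        dofs = do.call(rbind, lapply(j$dofs, as.data.frame))))
  acts <- lapply(doc$actuators, function(a)
    actuator(a$name,
             path = lapply(a$path, function(p)
               list(segment = p$segment, point = unlist(p$point))),
             m_musc = a$m_musc, l0 = a$l0, pennation = a$pennation,
             slack = a$slack, fmax = a$fmax,
             primary_segment = a$primary_segment, group = a$group,
             wrap = if (is.null(a$wrap)) NULL else list(
               segment = a$wrap$segment, center = unlist(a$wrap$center),
               axis = unlist(a$wrap$axis), radius = a$wrap$radius,
               between = unlist(a$wrap$between))))
  mat <- do.call(material_properties, doc$material)
  msk_model(segs, joints, acts, material = mat, body_mass = doc$body_mass,
            gravity = doc$gravity)
}

#' Write a gait trial as a delimited table
#'
#' One row per sample: `time`, coordinate columns (degrees for rotations,
#' metres for body translations), `grf_x/y/z` (N), and `cop_x/y/z` (m) when
#' present. Body mass and duty factor travel in a `# key: value` comment
#' header.
#'
#' @param trial a [gait_trial()].
#' @param path output CSV path.
#' @export
write_trial <- function(trial, path) {
  tab <- data.frame(time = trial$time, trial$angles,
                    grf_x = trial$grf[, 1L], grf_y = trial$grf[, 2L],
                    grf_z = trial$grf[, 3L], check.names = FALSE)
  if (!is.null(trial$cop)) {
    tab$cop_x <- trial$cop[, 1L]
    tab$cop_y <- trial$cop[, 2L]
    tab$cop_z <- trial$cop[, 3L]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# body_mass: ", format(trial$body_mass, digits = 15)),
               paste0("# duty_factor: ", format(trial$duty_factor,
                                                digits = 15))), con)
  utils::write.csv(tab, con, row.names = FALSE)
  invisible(path)
}

#' Read a gait trial written by [write_trial()]
#'
#' @param path CSV path.
#' @return a [gait_trial()] (markers are not round-tripped).
#' @export
read_trial <- function(path) {
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "#")]
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^#\\s*", "", h), ":\\s*")[[1L]]
    meta[[kv[1L]]] <- as.numeric(kv[2L])
  }
  tab <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  grf <- as.matrix(tab[, c("grf_x", "grf_y", "grf_z")])
  copc <- c("cop_x", "cop_y", "cop_z")
  cop <- if (all(copc %in% names(tab))) as.matrix(tab[, copc]) else NULL
  drop <- c("time", "grf_x", "grf_y", "grf_z", copc)
  ang <- as.matrix(tab[, setdiff(names(tab), drop), drop = FALSE])
  gait_trial(time = tab$time, angles = ang, grf = grf, cop = cop,
             body_mass = meta$body_mass, duty_factor = meta$duty_factor)
}

#' Read a cross-section outline from CSV
#'
#' Expects columns `y` and `z` in millimetres (converted to metres), with an
#' optional `part` column separating `outer` and `inner` outlines.
#'
#' @param path CSV path.
#' @return a [section_properties()] object.
#' @export
read_section <- function(path) {
  tab <- utils::read.csv(path)
  if (!all(c("y", "z") %in% names(tab)))
    stop("section CSV needs 'y' and 'z' columns (mm)")
  if ("part" %in% names(tab)) {
    outer <- as.matrix(tab[tab$part == "outer", c("y", "z")]) / 1000
    inner <- as.matrix(tab[tab$part == "inner", c("y", "z")]) / 1000
    if (!nrow(inner)) inner <- NULL
  } else {
    outer <- as.matrix(tab[, c("y", "z")]) / 1000
    inner <- NULL
  }
  section_properties(outer, inner)
}

#' Export a muscle solution as a tidy table
#'
#' @param solution a `muscle_solution`.
#' @return data frame in long format: `time`, `muscle`, `activation`,
#'   `force`.
#' @export
solution_table <- function(solution) {
  n <- length(solution$time)
  muscles <- colnames(solution$activations)
  data.frame(time = rep(solution$time, times = length(muscles)),
             muscle = rep(muscles, each = n),
             activation = as.numeric(solution$activations),
             force = as.numeric(solution$forces))
}

#' Export a stress trace as a tidy table
#'
#' @param trace a `stress_trace`.
#' @return data frame with `time`, the section loads and all stress
#'   components.
#' @export
stress_table <- function(trace) {
  cbind(data.frame(time = trace$time), as.data.frame(trace$loads),
        trace$stresses)
}
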