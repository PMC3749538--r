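# Clinical and mechanical read-outs: Cobb angles, disc stresses, screw
# pullout forces, and the validation report.

#' As-built state of a spine model
#'
#' @param model a `spine_model`.
#' @return object of class `spine_state` with vertebra orientations `R`,
#'   positions `p` and (if instrumented) the rod pose.
#' @export
as_built_state <- function(model) {
  structure(list(R = model$R0, p = model$p0,
                 rod = if (!is.null(model$rod)) model$rod$pose0 else NULL,
                 ref = diag(3)),
            class = "spine_state")
}

#' Cobb angle between two vertebral levels in a projection plane
#'
#' The endplate line of each end vertebra is taken from its rigid frame:
#' the local x-axis (endplate seen edge-on) for coronal measures, the
#' local y-axis for sagittal measures. Both lines are projected into the
#' named anatomical plane (coronal = XZ, sagittal = YZ of the patient
#' reference frame `state$ref`, which co-moves with the model under rigid
#' motions) and the angle between the projections is returned, unsigned,
#' with the signed value as attribute `"signed"`.
#'
#' @param state a `spine_state`.
#' @param upper_level,lower_level level names (upper must be cranial to
#'   lower).
#' @param plane `"coronal"` or `"sagittal"`.
#' @return angle in degrees, >= 0; attribute `signed` carries the sign.
#' @export
cobb_angle <- function(state, upper_level, lower_level,
                       plane = c("coronal", "sagittal")) {
  plane <- match.arg(plane)
  iu <- level_index(upper_level); il <- level_index(lower_level)
  if (is.na(iu) || is.na(il)) stop("unknown vertebral level")
  if (iu >= il) stop("upper_level must be cranial to lower_level")
  ax <- if (plane == "coronal") c(1, 0, 0) else c(0, 1, 0)
  proj <- if (plane == "coronal") c(1, 3) else c(2, 3)
  ref <- if (is.null(state$ref)) diag(3) else state$ref
  vu <- as.vector(t(ref) %*% state$R[[iu]] %*% ax)[proj]
  vl <- as.vector(t(ref) %*% state$R[[il]] %*% ax)[proj]
  s <- angle_signed_2d(vu, vl)
  structure(abs(s), signed = s)
}

#' Pullout force at a screw/vertebra interface
#'
#' The screw is rigid with its vertebra, so the bone-screw interface
#' reaction balances the linkage (rod) force on the screw head exactly.
#' The pullout force is the component of the rod force on the head along
#' the outward screw axis (positive = tending to extract the screw).
#'
#' @param sim a `spine_sim` simulation context.
#' @param k screw index.
#' @param state state to evaluate (defaults to the current one).
#' @return named vector with `pullout` (signed, N) and `magnitude` (N).
#' @export
pullout_force <- function(sim, k, state = sim$state) {
  f <- .linkage_force(sim, k, state)
  ax <- .screw_head(state, sim$model$screws[[k]])$axis_out
  c(pullout = sum(f * ax), magnitude = sqrt(sum(f * f)))
}

#' Measures of a single simulation state
#'
#' Angles use the model's configured end vertebrae; disc stresses come
#' from the lumped stress recovery; pullout forces are reported for every
#' placed screw (zero for screws not yet captured).
#'
#' @param sim a `spine_sim` context (or a bare `spine_model` for angle-only
#'   measures of an uninstrumented state).
#' @param state the state to measure.
#' @return object of class `measure_set`.
#' @export
per_step_measures <- function(sim, state = sim$state) {
  model <- if (inherits(sim, "spine_model")) sim else sim$model
  ml <- model$measure_levels
  ang <- c(main_cobb = as.numeric(cobb_angle(state, ml$main[1], ml$main[2], "coronal")),
           proximal_cobb = as.numeric(cobb_angle(state, ml$proximal[1], ml$proximal[2], "coronal")),
           kyphosis_T1_T12 = as.numeric(cobb_angle(state, ml$kyphosis[1], ml$kyphosis[2], "sagittal")),
           lordosis_L1_L5 = as.numeric(cobb_angle(state, ml$lordosis[1], ml$lordosis[2], "sagittal")))
  ds <- vapply(model$discs, function(d) disc_stress(state, d), 0)
  names(ds) <- vapply(model$discs, function(d)
    paste0(d$upper_level, "-", d$lower_level), "")
  po <- NULL
  if (!is.null(model$screws) && !inherits(sim, "spine_model")) {
    po <- t(vapply(seq_along(model$screws),
                   function(k) pullout_force(sim, k, state), c(pullout = 0, magnitude = 0)))
    rownames(po) <- vapply(model$screws, `[[`, "", "level")
  }
  structure(list(angles = ang, disc_stress = ds, pullout = po),
            class = "measure_set")
}

#' @export
print.measure_set <- function(x, ...) {
  cat(sprintf("Angles (deg): main %.1f proximal %.1f kyphosis %.1f lordosis %.1f\n",
              x$angles[1], x$angles[2], x$angles[3], x$angles[4]))
  cat(sprintf("Disc stress (MPa): max %.2f mean %.2f\n",
              max(x$disc_stress), mean(x$disc_stress)))
  if (!is.null(x$pullout))
    cat(sprintf("Pullout (N): max %.0f at %s\n",
                max(x$pullout[, "pullout"]),
                rownames(x$pullout)[which.max(x$pullout[, "pullout"])]))
  invisible(x)
}

# Disc region classification used for reporting: discs fully inside the
# instrumented spans versus the non-instrumented regions T1-T3, T6-T9 and
# L1-L5 used in the literature comparison.
disc_regions <- function() {
  segs <- paste0(spine_levels()[1:16], "-", spine_levels()[2:17])
  list(instrumented = segs[c(3:5, 9:12)],     # T3-T6 and T9-L1 spans
       T1_T3 = segs[1:2], T6_T9 = segs[6:8], L1_L5 = segs[13:16])
}

#' Region-averaged disc stresses over a trajectory
#'
#' Means over discs and over every converged equilibrium recorded by the
#' continuous monitoring (all load substeps, not only step-end states),
#' following the reporting convention: instrumented = discs spanned by
#' screws (T3-T6 and T9-L1), non-instrumented regions T1-T3, T6-T9,
#' L1-L5.
#'
#' @param traj a `spine_trajectory`.
#' @param monitor use the continuously monitored states (default TRUE;
#'   otherwise the step-end states only).
#' @return named numeric vector of region averages, MPa.
#' @export
region_stress_averages <- function(traj, monitor = TRUE) {
  reg <- disc_regions()
  S <- if (monitor && !is.null(traj$monitor))
    do.call(rbind, lapply(traj$monitor, `[[`, "stress"))
  else do.call(rbind, lapply(traj$steps, function(s) s$measures$disc_stress))
  out <- vapply(reg, function(levels) mean(S[, levels, drop = FALSE]), 0)
  out["non_instrumented"] <- mean(S[, unlist(reg[c("T1_T3", "T6_T9", "L1_L5")]),
                                    drop = FALSE])
  out
}

#' Monitored pullout forces over a trajectory
#'
#' @param traj a `spine_trajectory`.
#' @param monitor use the continuously monitored states (default TRUE).
#' @return matrix, one row per recorded equilibrium, one column per screw
#'   (signed pullout force, N), or NULL for an uninstrumented model.
#' @export
pullout_history <- function(traj, monitor = TRUE) {
  if (monitor && !is.null(traj$monitor)) {
    rows <- lapply(traj$monitor, `[[`, "pullout")
    rows <- rows[!vapply(rows, is.null, TRUE)]
    if (length(rows) == 0) return(NULL)
    return(do.call(rbind, rows))
  }
  rows <- lapply(traj$steps, function(s)
    if (is.null(s$measures$pullout)) NULL else s$measures$pullout[, "pullout"])
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) return(NULL)
  do.call(rbind, rows)
}

#' Validation envelope for the simulation read-outs
#'
#' @param disc_stress_bounds literature interval for non-instrumented disc
#'   stress averages, MPa.
#' @param pullout_upper pullout-force ceiling from published failure
#'   ranges, N.
#' @param angle_tolerance clinical angle tolerance, degrees.
#' @export
validation_envelope <- function(disc_stress_bounds = c(0.15, 2.6),
                                pullout_upper = 1892,
                                angle_tolerance = 5) {
  stopifnot(disc_stress_bounds[1] <= disc_stress_bounds[2])
  structure(list(disc_stress_bounds = disc_stress_bounds,
                 pullout_upper = pullout_upper,
                 angle_tolerance = angle_tolerance),
            class = "validation_envelope")
}

#' Validation report of a completed surgical trajectory
#'
#' Checks postoperative angles against targets, pullout forces against the
#' published ceiling, region stress averages against the literature
#' envelope, and identifies the peak-pullout step of every screw.
#'
#' @param traj a `spine_trajectory`.
#' @param envelope a [validation_envelope()].
#' @param targets optional named vector of postoperative angle targets
#'   (degrees) with names among `main_cobb`, `kyphosis_T1_T12`,
#'   `lordosis_L1_L5`.
#' @return object of class `validation_report`.
#' @export
validation_report <- function(traj, envelope = validation_envelope(),
                              targets = NULL) {
  if (length(traj$steps) == 0) {
    rep <- list(evaluated = FALSE,
                criteria = c(angles = "not evaluated",
                             pullout = "not evaluated",
                             stress = "not evaluated"))
    class(rep) <- "validation_report"
    return(rep)
  }
  fin <- traj$steps[[length(traj$steps)]]$measures
  ang <- fin$angles
  angle_ok <- NA
  angle_tab <- NULL
  if (!is.null(targets)) {
    angle_tab <- data.frame(target = targets,
                            simulated = ang[names(targets)],
                            row.names = names(targets))
    angle_ok <- all(abs(angle_tab$simulated - angle_tab$target) <=
                      envelope$angle_tolerance)
  }
  po <- do.call(rbind, lapply(traj$steps, function(s)
    if (is.null(s$measures$pullout)) NULL else s$measures$pullout[, "pullout"]))
  max_po <- if (is.null(po)) 0 else max(po)
  peak_step <- if (is.null(po)) NULL else {
    ps <- apply(po, 2, which.max)
    data.frame(screw = colnames(po),
               peak_step = vapply(traj$steps[ps], `[[`, "", "label"),
               peak_force = apply(po, 2, max), row.names = NULL)
  }
  st <- region_stress_averages(traj)
  nonin <- st[c("T1_T3", "T6_T9", "L1_L5")]
  rep <- list(
    evaluated = TRUE,
    angles = angle_tab, angles_pass = angle_ok,
    pullout_max = max_po,
    pullout_pass = max_po <= envelope$pullout_upper,
    pullout_peaks = peak_step,
    stress_regions = st,
    stress_noninstrumented_pass =
      all(nonin >= envelope$disc_stress_bounds[1] &
          nonin <= envelope$disc_stress_bounds[2]),
    stress_ordering_pass = st["instrumented"] > st["non_instrumented"],
    envelope = envelope)
  class(rep) <- "validation_report"
  rep
}

#' @export
print.validation_report <- function(x, ...) {
  if (!x$evaluated) {
    cat("Validation report: trajectory empty, all criteria not evaluated\n")
    return(invisible(x))
  }
  cat("Validation report\n")
  if (!is.null(x$angles)) {
    cat(sprintf("  postoperative angles (tol %.0f deg): %s\n",
                x$envelope$angle_tolerance,
                if (isTRUE(x$angles_pass)) "PASS" else "FAIL"))
    print(round(x$angles, 1))
  }
  cat(sprintf("  max pullout %.0f N (ceiling %.0f): %s\n", x$pullout_max,
              x$envelope$pullout_upper, if (x$pullout_pass) "PASS" else "FAIL"))
  cat(sprintf("  non-instrumented disc stress in [%.2f, %.2f] MPa: %s\n",
              x$envelope$disc_stress_bounds[1], x$envelope$disc_stress_bounds[2],
              if (x$stress_noninstrumented_pass) "PASS" else "FAIL"))
  cat(sprintf("  instrumented > non-instrumented stress: %s\n",
              if (x$stress_ordering_pass) "PASS" else "FAIL"))
  cat("  region averages (MPa):\n")
  print(round(x$stress_regions, 3))
  if (!is.null(x$pullout_peaks)) {
    cat("  pullout peaks per screw:\n")
    print(transform(x$pullout_peaks, peak_force = round(peak_force, 1)))
  }
  invisible(x)
}
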