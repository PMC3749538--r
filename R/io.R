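# Case configuration (YAML/JSON), the reference surgical case, and
# geometry/state exports.

.case_defaults <- function() {
  list(
    profile = list(main_thoracic_cobb = 0, proximal_thoracic_cobb = 0,
                   kyphosis_T1_T12 = 0, lordosis_L1_L5 = 0,
                   bending_cobb = NULL, bending_correction_pct = NULL),
    build = list(angle_tolerance = 5, seed = 1L, scale = 1, axial_coupling = 0),
    materials = list(E_annulus = 8, E_nucleus = 2, E_annulus_calibrated = 5,
                     poisson_disc = 0.45, nucleus_area_fraction = 0.4,
                     swap_moduli = FALSE,
                     ligament_stiffness = list(ALL = 23.75, PLL = 26.15,
                                               ISL = 9.8, LF = 22.6, CAP = 23.7)),
    implants = list(rod_diameter = 5.5, rod_modulus = 213, screw_modulus = 11,
                    screw_length = 40, head_cone_half_angle = 30),
    plan = list(screw_levels = c("T3", "T4", "T5", "T6",
                                 "T9", "T10", "T11", "T12", "L1"),
                postop_kyphosis = 26, postop_lordosis = 36,
                reduce_substeps = 10, derotate_increment = 1),
    seed = 1L
  )
}

.merge_checked <- function(defaults, given, path = "") {
  if (is.null(given)) return(defaults)
  unknown <- setdiff(names(given), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown config key%s: %s",
                 if (length(unknown) > 1) "s" else "",
                 paste0(path, unknown, collapse = ", ")))
  for (nm in names(given)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- .merge_checked(defaults[[nm]], as.list(given[[nm]]),
                                       paste0(path, nm, "."))
    } else {
      defaults[[nm]] <- given[[nm]]
    }
  }
  defaults
}

.validate_case <- function(cfg) {
  ls <- unlist(cfg$materials$ligament_stiffness)
  if (any(ls <= 0)) stop("config field materials.ligament_stiffness: stiffnesses must be > 0")
  for (f in c("E_annulus", "E_nucleus", "E_annulus_calibrated"))
    if (cfg$materials[[f]] <= 0)
      stop(sprintf("config field materials.%s: must be > 0", f))
  if (cfg$implants$rod_diameter <= 0) stop("config field implants.rod_diameter: must be > 0")
  if (cfg$build$angle_tolerance <= 0) stop("config field build.angle_tolerance: must be > 0")
  ang <- unlist(cfg$profile[c("main_thoracic_cobb", "proximal_thoracic_cobb",
                              "kyphosis_T1_T12", "lordosis_L1_L5")])
  if (any(ang < 0 | ang > 120)) stop("config field profile: angles must lie in [0, 120]")
  cfg
}

#' Load a case configuration from YAML or JSON
#'
#' Unknown keys are rejected; missing keys are filled with the package
#' defaults (the reference-case parameter set). `load(dump(x))` is the
#' identity on normalized configurations.
#'
#' @param path file path ending in .yaml/.yml or .json.
#' @return object of class `case_config`.
#' @export
load_case <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else stop("config must be .yaml or .json")
  cfg <- .validate_case(.merge_checked(.case_defaults(), raw))
  class(cfg) <- "case_config"
  cfg
}

#' Write a case configuration
#' @param cfg a `case_config`.
#' @param path output path (.yaml or .json).
#' @export
dump_case <- function(cfg, path) {
  x <- unclass(cfg)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path)
  } else {
    writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null"),
               path)
  }
  invisible(path)
}

#' The reference surgical case
#'
#' The Lenke 2B double thoracic patient driving the package's validation:
#' preoperative main thoracic Cobb 73 deg, proximal 42, kyphosis 35,
#' lordosis 37; lateral bending to 40 deg (45% correction); concave-side
#' screws T3-T6 and T9-L1 with a 5.5 mm rod shaped to the postoperative
#' sagittal targets 26/36.
#'
#' @return object of class `case_config`.
#' @export
make_reference_case <- function() {
  cfg <- .case_defaults()
  cfg$profile <- list(main_thoracic_cobb = 73, proximal_thoracic_cobb = 42,
                      kyphosis_T1_T12 = 35, lordosis_L1_L5 = 37,
                      bending_cobb = 40, bending_correction_pct = 45)
  class(cfg) <- "case_config"
  cfg
}

#' Build the spine model described by a case configuration
#' @param cfg a `case_config`.
#' @param instrument attach screws/rod/linkages per the plan (default TRUE).
#' @param calibrated use the calibrated annulus modulus (default TRUE).
#' @return a `spine_model`.
#' @export
case_model <- function(cfg, instrument = TRUE, calibrated = TRUE) {
  mats <- material_library(
    E_annulus = cfg$materials$E_annulus,
    E_nucleus = cfg$materials$E_nucleus,
    E_annulus_calibrated = cfg$materials$E_annulus_calibrated,
    ligament_stiffness = unlist(cfg$materials$ligament_stiffness),
    poisson_disc = cfg$materials$poisson_disc,
    nucleus_area_fraction = cfg$materials$nucleus_area_fraction,
    swap_moduli = isTRUE(cfg$materials$swap_moduli))
  prof <- patient_profile(
    main_thoracic_cobb = cfg$profile$main_thoracic_cobb,
    proximal_thoracic_cobb = cfg$profile$proximal_thoracic_cobb,
    kyphosis_T1_T12 = cfg$profile$kyphosis_T1_T12,
    lordosis_L1_L5 = cfg$profile$lordosis_L1_L5,
    bending_cobb = if (is.null(cfg$profile$bending_cobb))
      cfg$profile$main_thoracic_cobb else cfg$profile$bending_cobb)
  bc <- build_config(angle_tolerance = cfg$build$angle_tolerance,
                     seed = cfg$build$seed, scale = cfg$build$scale,
                     axial_coupling = cfg$build$axial_coupling)
  model <- build_spine(prof, bc, mats)
  if (calibrated)
    model$discs <- create_discs(model, E_annulus = mats$E_annulus_calibrated)
  if (instrument) {
    spec <- implant_spec(rod_diameter = cfg$implants$rod_diameter,
                         rod_modulus = cfg$implants$rod_modulus,
                         screw_modulus = cfg$implants$screw_modulus,
                         screw_length = cfg$implants$screw_length,
                         head_cone_half_angle = cfg$implants$head_cone_half_angle)
    model <- instrument_spine(model, levels = cfg$plan$screw_levels,
                              postop_kyphosis = cfg$plan$postop_kyphosis,
                              postop_lordosis = cfg$plan$postop_lordosis,
                              spec = spec)
  }
  model
}

#' Run the full surgical pipeline described by a case configuration
#'
#' Builds the spine, calibrates the annulus modulus against the profile's
#' lateral-bending target (when present), instruments, runs the staged
#' surgical plan, and optionally writes per-step measures and the
#' validation report.
#'
#' @param cfg a `case_config`.
#' @param calibrate run the flexibility calibration (default TRUE when the
#'   profile carries a bending target; otherwise the configured calibrated
#'   annulus modulus is used directly).
#' @param out_dir optional output directory for `measures.csv` and
#'   `validation.json`.
#' @param moment flexibility-test moment, N.mm.
#' @return list with `model`, `calibration` (or NULL), `trajectory` and
#'   `report`.
#' @export
run_case <- function(cfg, calibrate = TRUE, out_dir = NULL, moment = 6000) {
  model <- case_model(cfg, instrument = FALSE, calibrated = FALSE)
  cal <- NULL
  do_cal <- calibrate && !is.null(cfg$profile$bending_cobb) &&
    cfg$profile$bending_cobb < cfg$profile$main_thoracic_cobb - 1e-9
  if (do_cal) {
    cal <- calibrate_flexibility(model, moment = moment)
    model$discs <- create_discs(model, E_annulus = cal$E_annulus)
  } else {
    model$discs <- create_discs(model,
      E_annulus = model$materials$E_annulus_calibrated)
  }
  spec <- implant_spec(rod_diameter = cfg$implants$rod_diameter,
                       rod_modulus = cfg$implants$rod_modulus,
                       screw_modulus = cfg$implants$screw_modulus,
                       screw_length = cfg$implants$screw_length,
                       head_cone_half_angle = cfg$implants$head_cone_half_angle)
  model <- instrument_spine(model, levels = cfg$plan$screw_levels,
                            postop_kyphosis = cfg$plan$postop_kyphosis,
                            postop_lordosis = cfg$plan$postop_lordosis,
                            spec = spec)
  plan <- default_surgical_plan(
    reduce_substeps = cfg$plan$reduce_substeps,
    derotate_increment = cfg$plan$derotate_increment,
    kyphosis_target = cfg$plan$postop_kyphosis)
  traj <- run_surgery(model, plan)
  report <- validation_report(traj)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    measures_to_csv(traj, file.path(out_dir, "measures.csv"))
    writeLines(jsonlite::toJSON(list(
      final_angles = as.list(traj$steps[[length(traj$steps)]]$measures$angles),
      stress_regions = as.list(region_stress_averages(traj)),
      max_pullout = max(pullout_history(traj)),
      calibrated_annulus_MPa = if (is.null(cal)) NA else cal$E_annulus),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"),
      file.path(out_dir, "validation.json"))
  }
  list(model = model, calibration = cal, trajectory = traj, report = report)
}

# Oriented-box vertices of vertebra i in a state (8 x 3).
.vertebra_box <- function(model, state, i) {
  tab <- model$table
  hw <- tab$body_width[i] / 2; hd <- tab$body_depth[i] / 2
  hh <- tab$body_height[i] / 2
  corners <- as.matrix(expand.grid(x = c(-hw, hw), y = c(-hd, hd),
                                   z = c(-hh, hh)))
  t(apply(corners, 1, function(v)
    state$p[[i]] + as.vector(state$R[[i]] %*% v)))
}

.rod_polyline_global <- function(model, state, n = 100) {
  rod <- model$rod
  pose <- if (!is.null(state$rod)) state$rod else rod$pose0
  ss <- seq(0, rod$length, length.out = n)
  P <- t(vapply(1:3, function(j) stats::approx(rod$s, rod$pts[, j], xout = ss)$y,
                numeric(n)))
  t(pose$R %*% P + pose$t)
}

#' Export a model state as OBJ, VTK or JSON
#'
#' OBJ and VTK write each vertebra as an oriented box and the rod (if
#' instrumented) as a polyline; JSON serializes the state at full
#' precision so that re-import reproduces it bit-exactly.
#'
#' @param model a `spine_model`.
#' @param state the state to export.
#' @param path output file.
#' @param format one of "OBJ", "VTK", "JSON".
#' @return `path`, invisibly.
#' @export
export_state <- function(model, state, path, format = c("OBJ", "VTK", "JSON")) {
  format <- match.arg(toupper(format), c("OBJ", "VTK", "JSON"))
  box_faces <- matrix(c(1, 2, 4, 3,  5, 6, 8, 7,  1, 2, 6, 5,
                        3, 4, 8, 7,  1, 3, 7, 5,  2, 4, 8, 6),
                      ncol = 4, byrow = TRUE)
  if (format == "JSON") {
    # doubles written with 17 significant digits reimport bit-exactly
    num <- function(v) paste0("[", paste(sprintf("%.17g", v), collapse = ","), "]")
    arr <- function(rows) paste0("[", paste(vapply(rows, num, ""), collapse = ","), "]")
    rod <- if (is.null(state$rod)) "null" else
      paste0('{"R":', num(as.vector(state$rod$R)),
             ',"t":', num(state$rod$t), "}")
    writeLines(paste0('{"R":', arr(lapply(state$R, as.vector)),
                      ',"p":', arr(state$p), ',"rod":', rod, "}"), path)
    return(invisible(path))
  }
  boxes <- lapply(1:17, function(i) .vertebra_box(model, state, i))
  rodp <- if (!is.null(model$rod)) .rod_polyline_global(model, state) else NULL
  if (format == "OBJ") {
    con <- file(path, "w"); on.exit(close(con))
    nv <- 0
    for (i in 1:17) {
      B <- boxes[[i]]
      writeLines(sprintf("o vertebra_%s", model$table$level[i]), con)
      writeLines(sprintf("v %.6f %.6f %.6f", B[, 1], B[, 2], B[, 3]), con)
      writeLines(apply(box_faces + nv, 1, function(f)
        paste("f", paste(f, collapse = " "))), con)
      nv <- nv + 8
    }
    if (!is.null(rodp)) {
      writeLines("o rod", con)
      writeLines(sprintf("v %.6f %.6f %.6f", rodp[, 1], rodp[, 2], rodp[, 3]), con)
      writeLines(paste("l", paste(nv + seq_len(nrow(rodp)), collapse = " ")), con)
    }
  } else {
    pts <- do.call(rbind, boxes)
    if (!is.null(rodp)) pts <- rbind(pts, rodp)
    polys <- do.call(rbind, lapply(0:16, function(i) box_faces + 8 * i)) - 1
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c("# vtk DataFile Version 3.0", "spine state", "ASCII",
                 "DATASET POLYDATA",
                 sprintf("POINTS %d float", nrow(pts))), con)
    writeLines(sprintf("%.6f %.6f %.6f", pts[, 1], pts[, 2], pts[, 3]), con)
    writeLines(sprintf("POLYGONS %d %d", nrow(polys), 5 * nrow(polys)), con)
    writeLines(apply(polys, 1, function(f)
      paste(c(4, f), collapse = " ")), con)
    if (!is.null(rodp)) {
      idx <- (nrow(pts) - nrow(rodp)):(nrow(pts) - 1)
      writeLines(sprintf("LINES 1 %d", 1 + length(idx)), con)
      writeLines(paste(c(length(idx), idx), collapse = " "), con)
    }
  }
  invisible(path)
}

#' Import a JSON state written by [export_state()]
#' @param path JSON file.
#' @return a `spine_state`.
#' @export
import_state <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  R <- lapply(seq_len(nrow(obj$R)), function(i) matrix(obj$R[i, ], 3, 3))
  p <- lapply(seq_len(nrow(obj$p)), function(i) obj$p[i, ])
  rod <- if (!is.null(obj$rod))
    list(R = matrix(obj$rod$R, 3, 3), t = obj$rod$t) else NULL
  structure(list(R = R, p = p, rod = rod), class = "spine_state")
}

#' Write per-step measures of a trajectory to CSV
#'
#' One row per (step, quantity): angles, per-disc stresses and per-screw
#' pullout forces.
#'
#' @param traj a `spine_trajectory`.
#' @param path output CSV path.
#' @export
measures_to_csv <- function(traj, path) {
  rows <- list()
  for (s in traj$steps) {
    m <- s$measures
    rows[[length(rows) + 1]] <- data.frame(
      step = s$label, kind = "angle", name = names(m$angles),
      value = as.numeric(m$angles))
    rows[[length(rows) + 1]] <- data.frame(
      step = s$label, kind = "disc_stress", name = names(m$disc_stress),
      value = as.numeric(m$disc_stress))
    if (!is.null(m$pullout))
      rows[[length(rows) + 1]] <- data.frame(
        step = s$label, kind = "pullout", name = rownames(m$pullout),
        value = m$pullout[, "pullout"])
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
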