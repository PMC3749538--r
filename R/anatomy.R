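# Parametric anatomy: vertebral morphometry, patient profiles, and
# construction of the T1-L5 rigid-vertebra chain from angular targets.

#' Vertebral levels modelled by the package
#'
#' @return character vector of the 17 levels, ordered cranial to caudal
#'   (T1 ... T12, L1 ... L5).
#' @export
spine_levels <- function() c(paste0("T", 1:12), paste0("L", 1:5))

#' Default vertebral morphometric table
#'
#' Body dimensions are graded linearly from T1 to L5 (heights 16 to 29 mm,
#' widths 26 to 50 mm, depths 18 to 35 mm), consistent with adult
#' thoracolumbar morphometry. The pedicle entry offsets locate the screw
#' head relative to the body centroid in the local vertebral frame
#' (+X left, +Y anterior, +Z cranial). `disc_height` is the height of the
#' disc caudal to the level (NA for L5).
#'
#' @param scale overall volumetric scale factor applied to all linear
#'   dimensions (default 1).
#' @return data.frame with one row per level.
#' @export
vertebra_table <- function(scale = 1) {
  n <- 17L
  g <- (seq_len(n) - 1) / (n - 1)
  tab <- data.frame(
    level = spine_levels(),
    body_height = scale * (16 + g * (29 - 16)),
    body_width  = scale * (26 + g * (50 - 26)),
    body_depth  = scale * (18 + g * (35 - 18)),
    pedicle_lateral   = scale * (12 + g * 4),          # |x| of screw head
    pedicle_posterior = scale * (10 + g * 4),          # extra -y beyond body
    disc_height = c(scale * (5 + (seq_len(n - 1) - 1) / (n - 2) * (11 - 5)), NA),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- tab$level
  tab
}

#' Patient angular profile
#'
#' Holds the coronal and sagittal targets describing a scoliotic spine:
#' main and proximal thoracic Cobb angles, T1-T12 kyphosis, L1-L5 lordosis,
#' and the lateral-bending flexibility of the main curve.
#'
#' @param main_thoracic_cobb main thoracic coronal Cobb angle, degrees.
#' @param proximal_thoracic_cobb proximal thoracic coronal Cobb, degrees.
#' @param kyphosis_T1_T12 sagittal kyphosis T1-T12, degrees.
#' @param lordosis_L1_L5 sagittal lordosis L1-L5, degrees.
#' @param bending_cobb main-curve Cobb reached in the lateral bending
#'   (flexibility) test, degrees; must not exceed the main Cobb.
#' @param bending_correction_pct percent correction in bending (redundant
#'   with `bending_cobb`; kept for reporting).
#' @return object of class `patient_profile`.
#' @export
patient_profile <- function(main_thoracic_cobb = 0,
                            proximal_thoracic_cobb = 0,
                            kyphosis_T1_T12 = 0,
                            lordosis_L1_L5 = 0,
                            bending_cobb = main_thoracic_cobb,
                            bending_correction_pct = if (main_thoracic_cobb > 0)
                              100 * (1 - bending_cobb / main_thoracic_cobb) else 0) {
  p <- list(main_thoracic_cobb = main_thoracic_cobb,
            proximal_thoracic_cobb = proximal_thoracic_cobb,
            kyphosis_T1_T12 = kyphosis_T1_T12,
            lordosis_L1_L5 = lordosis_L1_L5,
            bending_cobb = bending_cobb,
            bending_correction_pct = bending_correction_pct)
  angs <- unlist(p[1:4])
  if (any(!is.finite(angs)) || any(angs < 0) || any(angs > 120))
    stop("profile angles must lie in [0, 120] degrees")
  if (bending_cobb > main_thoracic_cobb + 1e-9)
    stop("bending_cobb cannot exceed main_thoracic_cobb")
  class(p) <- "patient_profile"
  p
}

#' @export
print.patient_profile <- function(x, ...) {
  cat("Patient profile (degrees):\n")
  cat(sprintf("  main thoracic Cobb     %6.1f\n", x$main_thoracic_cobb))
  cat(sprintf("  proximal thoracic Cobb %6.1f\n", x$proximal_thoracic_cobb))
  cat(sprintf("  kyphosis T1-T12        %6.1f\n", x$kyphosis_T1_T12))
  cat(sprintf("  lordosis L1-L5         %6.1f\n", x$lordosis_L1_L5))
  cat(sprintf("  bending Cobb           %6.1f (%.0f%% correction)\n",
              x$bending_cobb, x$bending_correction_pct))
  invisible(x)
}

#' Build configuration for the spine constructor
#'
#' @param angle_tolerance admissible deviation, in degrees, between the
#'   measured angles of the built model and the profile targets (default 5,
#'   the build tolerance used for validation against radiographs).
#' @param seed integer seed controlling any stochastic fixtures.
#' @param dimension_table morphometric table as from [vertebra_table()].
#' @param scale volumetric scale passed to the default table.
#' @param axial_coupling apical axial rotation coupled to the local coronal
#'   wedge (dimensionless factor; default 0 = no axial rotation).
#' @return object of class `build_config`.
#' @export
build_config <- function(angle_tolerance = 5, seed = 1L,
                         dimension_table = NULL, scale = 1,
                         axial_coupling = 0) {
  if (angle_tolerance <= 0) stop("angle_tolerance must be > 0")
  if (is.null(dimension_table)) dimension_table <- vertebra_table(scale)
  stopifnot(nrow(dimension_table) == 17L,
            identical(dimension_table$level, spine_levels()))
  if (any(dimension_table$body_height <= 0) ||
      any(dimension_table$body_width <= 0) ||
      any(dimension_table$body_depth <= 0))
    stop("all vertebral dimensions must be positive")
  structure(list(angle_tolerance = angle_tolerance, seed = as.integer(seed),
                 dimension_table = dimension_table,
                 axial_coupling = axial_coupling),
            class = "build_config")
}

# Curve definitions: which inter-vertebral segments carry each curve's
# wedge rotations, which end vertebrae measure it, and the rotation axis.
# Segment j joins vertebra j to vertebra j+1 (j = 1..16).
curve_spans <- function() {
  list(
    proximal = list(segments = 1:5,  measure = c("T1", "T5"),
                    plane = "coronal", sign = +1),
    main     = list(segments = 5:12, measure = c("T6", "T12"),
                    plane = "coronal", sign = -1),
    kyphosis = list(segments = 1:11, measure = c("T1", "T12"),
                    plane = "sagittal", sign = +1),
    lordosis = list(segments = 13:16, measure = c("L1", "L5"),
                    plane = "sagittal", sign = -1)
  )
}

# Raised-cosine bell weights over n segments (sum 1): smooth apical
# concentration, near-zero wedges at the curve ends.
cosine_bell <- function(n) {
  w <- 1 - cos(2 * pi * (seq_len(n) - 0.5) / n)
  w / sum(w)
}

level_index <- function(level) match(level, spine_levels())

# Measured angle of a single-plane wedge chain between two levels: for
# rotations confined to one plane this is exactly the sum of the wedges
# strictly between the measurement vertebrae.
.plane_chain_angle <- function(wedges, measure) {
  iu <- level_index(measure[1]); il <- level_index(measure[2])
  sum(wedges[iu:(il - 1)])
}

#' Solve inter-vertebral transforms reproducing a patient profile
#'
#' Distributes per-segment wedge rotations over curve-specific level ranges
#' with raised-cosine weighting and solves one scale factor per curve by
#' bisection (0.01 degree tolerance) so that each curve, taken in its own
#' plane, measures exactly its target between the curve's end vertebrae.
#' The four curves are then composed in 3D; because finite rotations do not
#' commute, the measured projected angles of the composed chain fall
#' slightly short of the in-plane targets (a few degrees for severe curves),
#' which is the behaviour of real radiographic measures and must stay within
#' `config$angle_tolerance`.
#'
#' @param targets a [patient_profile()].
#' @param config a [build_config()].
#' @return list with `wedges` (16 x 3 matrix of per-segment rotation vectors,
#'   radians, columns = rotations about X, Y, Z) and `heights` (16 segment
#'   centre-to-centre distances, mm).
#' @export
solve_profile_transforms <- function(targets, config = build_config()) {
  spans <- curve_spans()
  tgt <- c(proximal = targets$proximal_thoracic_cobb,
           main = targets$main_thoracic_cobb,
           kyphosis = targets$kyphosis_T1_T12,
           lordosis = targets$lordosis_L1_L5)
  scales <- numeric(length(spans)); names(scales) <- names(spans)
  weights <- list()
  for (nm in names(spans)) {
    sp <- spans[[nm]]
    w <- numeric(16)
    w[sp$segments] <- cosine_bell(length(sp$segments))
    weights[[nm]] <- w
    target <- tgt[[nm]]
    if (target < 1e-12) { scales[nm] <- 0; next }
    # bisection on the curve scale: in-plane measured angle is monotone in s
    f <- function(s) .plane_chain_angle(s * w, sp$measure) - target
    lo <- 0; hi <- 2 * target / max(.plane_chain_angle(w, sp$measure), 1e-12)
    while (f(hi) < 0) hi <- hi * 2
    while (hi - lo > 1e-9 && abs(f((lo + hi) / 2)) > 0.005) {
      mid <- (lo + hi) / 2
      if (f(mid) < 0) lo <- mid else hi <- mid
    }
    scales[nm] <- (lo + hi) / 2
  }
  compose_wedges <- function(scales) {
    wedges <- matrix(0, 16, 3, dimnames = list(NULL, c("x", "y", "z")))
    for (nm in names(spans)) {
      sp <- spans[[nm]]
      ax <- if (sp$plane == "coronal") "y" else "x"
      wedges[, ax] <- wedges[, ax] + sp$sign * deg2rad(scales[nm] * weights[[nm]])
    }
    wedges
  }
  # two anatomical corrections below the thoracic curves:
  # (a) composing coronal and sagittal wedges generates a spurious axial
  #     twist; a compensating axial wedge at the thoracolumbar junction
  #     keeps the lumbar spine axially neutral;
  # (b) a compensatory lumbar coronal curve levels L5 under the tilted
  #     lower end vertebra of the main curve, as in balanced scoliosis
  detwist <- function(wedges) {
    # compensatory lumbar coronal curve: levels L5 under the tilted lower
    # end vertebra of the main curve, as in balanced scoliosis
    for (rep in 1:3) {
      R <- diag(3)
      for (j in 1:16) R <- R %*% rot_exp(wedges[j, ])
      v <- (R %*% c(1, 0, 0))[c(1, 3)]
      phi <- atan2(v[2], v[1])         # coronal tilt of L5
      if (abs(phi) < 1e-6) break
      wedges[13:16, "y"] <- wedges[13:16, "y"] + cosine_bell(4) * phi
    }
    wedges
  }
  measure_chain <- function(wedges) {
    R <- diag(3)
    Rs <- vector("list", 17); Rs[[1]] <- R
    for (j in 1:16) Rs[[j + 1]] <- Rs[[j]] %*% rot_exp(wedges[j, ])
    vapply(names(spans), function(nm) {
      sp <- spans[[nm]]
      iu <- level_index(sp$measure[1]); il <- level_index(sp$measure[2])
      ax <- if (sp$plane == "coronal") c(1, 0, 0) else c(0, 1, 0)
      pr <- if (sp$plane == "coronal") c(1, 3) else c(2, 3)
      angle_between_2d(as.vector(Rs[[iu]] %*% ax)[pr],
                       as.vector(Rs[[il]] %*% ax)[pr])
    }, 0)
  }
  # the composed 3D chain measures a few degrees short of the in-plane
  # targets for severe combined deformities (finite rotations do not
  # commute); refine the curve scales only while some measure falls
  # outside the build tolerance, mirroring a build-to-tolerance protocol
  wedges <- detwist(compose_wedges(scales))
  best <- list(err = Inf, wedges = wedges)
  for (it in 1:25) {
    meas <- measure_chain(wedges)
    err <- max(abs(meas - tgt))
    if (err < best$err) best <- list(err = err, wedges = wedges)
    if (all(abs(meas - tgt) <= config$angle_tolerance)) break
    # damped, clamped multiplicative update: the measured projections
    # respond non-linearly (and can saturate) for severe deformities
    adj <- ifelse(tgt > 1e-9 & meas > 1e-9, (tgt / pmax(meas, 1e-9))^0.7, 1)
    adj <- pmin(pmax(adj, 0.7), 1.4)
    scales <- scales * adj
    wedges <- detwist(compose_wedges(scales))
  }
  wedges <- best$wedges
  if (config$axial_coupling != 0) {
    main <- spans$main
    w <- numeric(16); w[main$segments] <- cosine_bell(length(main$segments))
    wedges[, "z"] <- config$axial_coupling * wedges[, "y"]
  }
  tab <- config$dimension_table
  heights <- tab$body_height[1:16] / 2 + tab$disc_height[1:16] +
    tab$body_height[2:17] / 2
  list(wedges = wedges, heights = heights)
}

#' Build the rigid-vertebra spine model
#'
#' Constructs the 17-vertebra chain whose projected coronal and sagittal
#' angles reproduce the profile targets within the build tolerance, attaches
#' disc and ligament elements with zero prestrain, and records the boundary
#' conditions (T1 transversely constrained, L5 fixed except coronal
#' rotation).
#'
#' @param profile a [patient_profile()].
#' @param config a [build_config()].
#' @param materials a [material_library()]; annulus modulus taken from
#'   `E_annulus` (use [calibrate_flexibility()] to adapt it).
#' @return object of class `spine_model`.
#' @export
build_spine <- function(profile, config = build_config(),
                        materials = material_library()) {
  tr <- solve_profile_transforms(profile, config)
  tab <- config$dimension_table
  R <- vector("list", 17); p <- vector("list", 17)
  R[[1]] <- diag(3); p[[1]] <- c(0, 0, 0)
  for (j in 1:16) {
    S <- rot_exp(tr$wedges[j, ])
    Rmid <- R[[j]] %*% rot_exp(tr$wedges[j, ] / 2)
    p[[j + 1]] <- p[[j]] - as.vector(Rmid %*% c(0, 0, tr$heights[j]))
    R[[j + 1]] <- R[[j]] %*% S
  }
  # place L5 at the origin; orientations keep the patient-anatomical
  # reference (L5 frame = global frame), in which all projected angles
  # are measured
  pL5 <- p[[17]]
  for (i in 1:17) p[[i]] <- p[[i]] - pL5
  model <- structure(list(
    profile = profile, config = config, table = tab, materials = materials,
    R0 = R, p0 = p,
    wedges = tr$wedges, heights = tr$heights,
    measure_levels = lapply(curve_spans(), `[[`, "measure"),
    boundary = list(T1 = c("tx", "ty"), L5 = c("tx", "ty", "tz", "rx", "rz")),
    concave_side = +1   # +X (patient left) for the right main thoracic curve
  ), class = "spine_model")
  model$discs <- create_discs(model)
  model$ligaments <- create_ligaments(model)
  model$ligA <- .ligament_arrays(model$ligaments)
  st <- as_built_state(model)
  meas <- c(main = cobb_angle(st, "T6", "T12", "coronal"),
            proximal = cobb_angle(st, "T1", "T5", "coronal"),
            kyphosis = cobb_angle(st, "T1", "T12", "sagittal"),
            lordosis = cobb_angle(st, "L1", "L5", "sagittal"))
  tgtv <- c(main = profile$main_thoracic_cobb,
            proximal = profile$proximal_thoracic_cobb,
            kyphosis = profile$kyphosis_T1_T12,
            lordosis = profile$lordosis_L1_L5)
  resid <- meas - tgtv
  if (any(abs(resid) > config$angle_tolerance)) {
    stop(sprintf(
      "profile fitting did not converge within %.1f deg; residuals: %s",
      config$angle_tolerance,
      paste(sprintf("%s %+0.1f", names(resid), resid), collapse = ", ")))
  }
  model$as_built_measures <- meas
  model
}

#' @export
print.spine_model <- function(x, ...) {
  cat("Osteoligamentous spine model, T1-L5 (17 rigid vertebrae)\n")
  cat(sprintf("  discs: %d   ligaments: %d (tension-only)\n",
              length(x$discs), length(x$ligaments)))
  m <- x$as_built_measures
  cat(sprintf("  as-built: main Cobb %.1f, proximal %.1f, kyphosis %.1f, lordosis %.1f deg\n",
              m["main"], m["proximal"], m["kyphosis"], m["lordosis"]))
  if (!is.null(x$screws))
    cat(sprintf("  instrumented: %d screws (%s), rod %.1f mm\n",
                length(x$screws),
                paste(vapply(x$screws, `[[`, "", "level"), collapse = ","),
                x$rod$diameter))
  invisible(x)
}

#' @export
summary.spine_model <- function(object, ...) {
  print(object)
  cat("\nProfile targets vs as-built measures (deg):\n")
  m <- object$as_built_measures
  t <- c(object$profile$main_thoracic_cobb, object$profile$proximal_thoracic_cobb,
         object$profile$kyphosis_T1_T12, object$profile$lordosis_L1_L5)
  df <- data.frame(target = t, built = as.numeric(m),
                   row.names = c("main Cobb", "proximal Cobb",
                                 "kyphosis T1-T12", "lordosis L1-L5"))
  print(round(df, 2))
  invisible(object)
}

#' Generate a synthetic scoliotic patient profile
#'
#' Draws a reproducible random profile from physiologic ranges. The
#' `lenke1` template is a single main thoracic curve with a minor
#' non-structural proximal curve; `lenke2` a double thoracic pattern with
#' the main curve always exceeding the proximal; `straight` a spine with
#' all angles zero.
#'
#' @param seed integer seed; identical seeds give identical profiles.
#' @param curve_template one of "lenke1", "lenke2", "straight".
#' @return a [patient_profile()].
#' @export
generate_synthetic_patient <- function(seed,
                                       curve_template = c("lenke2", "lenke1", "straight")) {
  curve_template <- match.arg(curve_template)
  if (curve_template == "straight")
    return(patient_profile(0, 0, 0, 0, 0, 0))
  rng <- local({
    set.seed(as.integer(seed))
    list(u = runif(6))
  })
  u <- rng$u
  main <- 45 + u[1] * 40                       # 45-85 deg
  prox <- if (curve_template == "lenke2") 25 + u[2] * (main - 35) * 0.8
          else 10 + u[2] * 15
  prox <- min(prox, main - 5)
  kyph <- 20 + u[3] * 30                       # 20-50
  lord <- 30 + u[4] * 30                       # 30-60
  corr <- 30 + u[5] * 30                       # 30-60 % flexibility
  patient_profile(main_thoracic_cobb = main,
                  proximal_thoracic_cobb = max(prox, 0),
                  kyphosis_T1_T12 = kyph,
                  lordosis_L1_L5 = lord,
                  bending_cobb = main * (1 - corr / 100),
                  bending_correction_pct = corr)
}
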