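# Lumped tissue mechanics: 6-DOF elastic disc couplers with stress
# recovery, and the five tension-only ligament sets.

#' Material library for discs and ligaments
#'
#' Disc moduli default to 8 MPa (annulus) and 2 MPa (nucleus); the
#' calibrated annulus value used by the default simulation is 5 MPa.
#' Ligament stiffnesses are per millimetre of elongation: anterior
#' longitudinal (ALL) 23.75, posterior longitudinal (PLL) 26.15,
#' interspinous (ISL) 9.8, ligamentum flavum (LF) 22.6 and capsular (CAP)
#' 23.7 N/mm. Units: mm, N, MPa throughout.
#'
#' @param E_annulus annulus modulus, MPa.
#' @param E_nucleus nucleus modulus, MPa.
#' @param E_annulus_calibrated annulus modulus after flexibility
#'   calibration, MPa.
#' @param ligament_stiffness named vector of N/mm stiffnesses.
#' @param poisson_disc Poisson ratio of the lumped disc.
#' @param nucleus_area_fraction fraction of the disc cross-section occupied
#'   by the nucleus.
#' @param swap_moduli if TRUE assign 2 MPa to the annulus and 8 MPa to the
#'   nucleus (the alternative reading of the two printed moduli).
#' @return object of class `material_library`.
#' @export
material_library <- function(E_annulus = 8, E_nucleus = 2,
                             E_annulus_calibrated = 5,
                             ligament_stiffness = c(ALL = 23.75, PLL = 26.15,
                                                    ISL = 9.8, LF = 22.6,
                                                    CAP = 23.7),
                             poisson_disc = 0.45,
                             nucleus_area_fraction = 0.4,
                             swap_moduli = FALSE) {
  if (swap_moduli) { tmp <- E_annulus; E_annulus <- E_nucleus; E_nucleus <- tmp }
  stopifnot(E_annulus > 0, E_nucleus > 0, E_annulus_calibrated > 0,
            all(ligament_stiffness > 0), poisson_disc > 0, poisson_disc < 0.5,
            nucleus_area_fraction > 0, nucleus_area_fraction < 1)
  need <- c("ALL", "PLL", "ISL", "LF", "CAP")
  if (!all(need %in% names(ligament_stiffness)))
    stop("ligament_stiffness must name ALL, PLL, ISL, LF, CAP")
  structure(list(E_annulus = E_annulus, E_nucleus = E_nucleus,
                 E_annulus_calibrated = E_annulus_calibrated,
                 ligament_stiffness = ligament_stiffness[need],
                 poisson_disc = poisson_disc,
                 nucleus_area_fraction = nucleus_area_fraction),
            class = "material_library")
}

# Effective composite modulus: area-weighted mean of annulus and nucleus.
.disc_Eeff <- function(materials, E_annulus = materials$E_annulus) {
  f <- materials$nucleus_area_fraction
  (1 - f) * E_annulus + f * materials$E_nucleus
}

#' 6x6 lumped stiffness matrix of an intervertebral disc
#'
#' Beam-on-elastic-segment formulas on the elliptical cross-section:
#' axial k = E A / h, shear k = G A / h with G = E / (2 (1 + nu)),
#' bending k = E I / h about each bending axis and torsion k = G J / h,
#' with the composite modulus E the area-weighted mean of annulus and
#' nucleus. Rows/columns ordered (Fx, Fy, Fz, Mx, My, Mz) in the disc
#' frame (x left, y anterior, z axial).
#'
#' @param a,b ellipse semi-axes, mm (a along x, b along y).
#' @param h disc height, mm.
#' @param materials a [material_library()].
#' @param E_annulus annulus modulus override, MPa (for calibration).
#' @return 6x6 diagonal stiffness matrix, N/mm and N.mm/rad blocks.
#' @export
disc_stiffness <- function(a, b, h, materials = material_library(),
                           E_annulus = materials$E_annulus) {
  if (h <= 0 || a <= 0 || b <= 0) stop("degenerate disc geometry")
  E <- .disc_Eeff(materials, E_annulus)
  G <- E / (2 * (1 + materials$poisson_disc))
  A <- pi * a * b
  Ix <- pi / 4 * a * b^3        # bending about x: fibre distance is y (c = b)
  Iy <- pi / 4 * a^3 * b
  J <- Ix + Iy
  diag(c(G * A / h, G * A / h, E * A / h,
         E * Ix / h, E * Iy / h, G * J / h))
}

#' Create the disc elements of a built spine model
#'
#' One six-degree-of-freedom elastic coupler per motion segment. Both
#' attachment frames are body-fixed and co-located at the disc mid-height
#' as built, so the as-built deflection (and hence energy) is exactly
#' zero and a pure relative rotation about the disc centre carries no
#' translational penalty (Euler-beam consistent coupling).
#'
#' @param model a `spine_model`.
#' @param E_annulus annulus modulus override, MPa (used by the
#'   flexibility calibration); defaults to the model's material library.
#' @return list of 16 disc elements.
#' @export
create_discs <- function(model, E_annulus = NULL) {
  tab <- model$table
  mats <- model$materials
  if (is.null(mats)) mats <- material_library()
  if (is.null(E_annulus)) E_annulus <- mats$E_annulus
  discs <- vector("list", 16)
  for (j in 1:16) {
    a <- (tab$body_width[j] + tab$body_width[j + 1]) / 4
    b <- (tab$body_depth[j] + tab$body_depth[j + 1]) / 4
    h <- tab$disc_height[j]
    # both attachment frames sit at the disc mid-height (co-located as
    # built): a pure relative rotation about the disc centre then carries
    # no translational penalty, giving Euler-beam bending/shear coupling
    r_up <- c(0, 0, -(tab$body_height[j] / 2 + h / 2))
    r_lo <- c(0, 0, tab$body_height[j + 1] / 2 + h / 2)
    Ru <- model$R0[[j]]; Rl <- model$R0[[j + 1]]
    o_up <- model$p0[[j]] + as.vector(Ru %*% r_up)
    o_lo <- model$p0[[j + 1]] + as.vector(Rl %*% r_lo)
    discs[[j]] <- list(
      upper = j, lower = j + 1,
      upper_level = tab$level[j], lower_level = tab$level[j + 1],
      a = a, b = b, area = pi * a * b, height = h,
      nucleus_area_fraction = mats$nucleus_area_fraction,
      r_upper = r_up, r_lower = r_lo,
      delta_t0 = as.vector(t(Rl) %*% (o_up - o_lo)),
      Qrel0 = t(Rl) %*% Ru,
      K = disc_stiffness(a, b, h, mats, E_annulus)
    )
  }
  discs
}

# Ligament attachment offsets in the local vertebral frame. `z` is +1 for
# the superior and -1 for the inferior attachment of the spanned segment.
.lig_offsets <- function(type, width, depth, height, z) {
  hz <- z * height / 2
  switch(type,
    ALL = c(0, depth / 2, hz),
    PLL = c(0, -depth / 2, hz),
    ISL = c(0, -(depth / 2 + 30), hz),
    LF  = c(0, -(depth / 2 + 15), hz),
    CAPL = c(15, -(depth / 2 + 10), hz),
    CAPR = c(-15, -(depth / 2 + 10), hz)
  )
}

#' Create the tension-only ligament set of a spine model
#'
#' Five ligament types per motion segment with the capsular ligaments
#' bilateral, giving six elements per segment and 96 in total for T1-L5.
#' Rest lengths equal the as-built attachment distances (zero prestrain).
#'
#' @param model a `spine_model`.
#' @return list of ligament elements.
#' @export
create_ligaments <- function(model) {
  tab <- model$table
  mats <- model$materials
  if (is.null(mats)) mats <- material_library()
  ks <- mats$ligament_stiffness
  types <- c("ALL", "PLL", "ISL", "LF", "CAPL", "CAPR")
  kmap <- c(ALL = ks[["ALL"]], PLL = ks[["PLL"]], ISL = ks[["ISL"]],
            LF = ks[["LF"]], CAPL = ks[["CAP"]], CAPR = ks[["CAP"]])
  ligs <- list()
  for (j in 1:16) {
    for (ty in types) {
      r_up <- .lig_offsets(ty, tab$body_width[j], tab$body_depth[j],
                           tab$body_height[j], z = -1)
      r_lo <- .lig_offsets(ty, tab$body_width[j + 1], tab$body_depth[j + 1],
                           tab$body_height[j + 1], z = +1)
      p_up <- model$p0[[j]] + as.vector(model$R0[[j]] %*% r_up)
      p_lo <- model$p0[[j + 1]] + as.vector(model$R0[[j + 1]] %*% r_lo)
      L0 <- sqrt(sum((p_up - p_lo)^2))
      ligs[[length(ligs) + 1]] <- list(
        type = sub("^CAP[LR]$", "CAP", ty), side = ty,
        upper = j, lower = j + 1, stiffness = unname(kmap[[ty]]),
        r_upper = r_up, r_lower = r_lo, rest_length = L0)
    }
  }
  ligs
}

#' Tension-only ligament force
#'
#' @param lig a ligament element (see [create_ligaments()]).
#' @param current_length current attachment distance, mm.
#' @return tensile force in N: `stiffness * max(0, current_length -
#'   rest_length)`; slack ligaments carry exactly zero.
#' @export
ligament_force <- function(lig, current_length) {
  stopifnot(current_length >= 0)
  lig$stiffness * max(0, current_length - lig$rest_length)
}

# Relative 6-DOF deflection of a disc in the caudal endplate frame.
.disc_delta <- function(state, disc) {
  Ru <- state$R[[disc$upper]]; Rl <- state$R[[disc$lower]]
  o_up <- state$p[[disc$upper]] + as.vector(Ru %*% disc$r_upper)
  o_lo <- state$p[[disc$lower]] + as.vector(Rl %*% disc$r_lower)
  dt <- as.vector(t(Rl) %*% (o_up - o_lo)) - disc$delta_t0
  D <- t(Rl) %*% Ru %*% t(disc$Qrel0)
  dr <- rot_log(D)
  list(delta = c(dt, dr), o_up = o_up, o_lo = o_lo, C = Rl, dr = dr)
}

#' Wrench transmitted by a disc element
#'
#' @param state a spine state (lists `R`, `p`).
#' @param disc a disc element.
#' @return 6-vector (Fx, Fy, Fz, Mx, My, Mz) in the disc frame: the
#'   stiffness matrix times the relative 6-DOF deflection of the two
#'   attachment frames; acts equal and opposite on the two vertebrae.
#' @export
disc_wrench <- function(state, disc) {
  d <- .disc_delta(state, disc)
  as.vector(disc$K %*% d$delta)
}

#' Von Mises stress estimate recovered from a disc wrench
#'
#' Lumped-element stress recovery on the elliptical section:
#' sigma = |Fz|/A + |Mx| b/Ix + |My| a/Iy (axial plus bending fibre
#' stress), tau = |Fshear|/A + |Mz| rmax/J, and the scalar von Mises
#' equivalent sqrt(sigma^2 + 3 tau^2). Reduces to |Fz|/A under pure axial
#' load.
#'
#' @param state a spine state.
#' @param disc a disc element.
#' @return scalar stress, MPa.
#' @export
disc_stress <- function(state, disc) {
  w <- disc_wrench(state, disc)
  A <- disc$area
  Ix <- pi / 4 * disc$a * disc$b^3
  Iy <- pi / 4 * disc$a^3 * disc$b
  J <- Ix + Iy
  sigma <- abs(w[3]) / A + abs(w[4]) * disc$b / Ix + abs(w[5]) * disc$a / Iy
  tau <- sqrt(w[1]^2 + w[2]^2) / A + abs(w[6]) * max(disc$a, disc$b) / J
  sqrt(sigma^2 + 3 * tau^2)
}

# Column-bound ligament arrays for vectorized energy evaluation.
.ligament_arrays <- function(ligs) {
  list(iu = as.integer(vapply(ligs, `[[`, 0, "upper")),
       il = as.integer(vapply(ligs, `[[`, 0, "lower")),
       r_up = t(vapply(ligs, `[[`, numeric(3), "r_upper")),
       r_lo = t(vapply(ligs, `[[`, numeric(3), "r_lower")),
       k = vapply(ligs, `[[`, 0, "stiffness"),
       L0 = vapply(ligs, `[[`, 0, "rest_length"))
}

# Current attachment distance of a ligament.
.lig_length <- function(state, lig) {
  p_up <- state$p[[lig$upper]] + as.vector(state$R[[lig$upper]] %*% lig$r_upper)
  p_lo <- state$p[[lig$lower]] + as.vector(state$R[[lig$lower]] %*% lig$r_lower)
  sqrt(sum((p_up - p_lo)^2))
}
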