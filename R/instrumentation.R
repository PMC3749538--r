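# Instrumentation: pedicle screws, the shaped rod, polyaxial capture cone
# and the screw-rod artificial linkages.

#' Implant specification
#'
#' @param rod_diameter rod diameter, mm (default 5.5).
#' @param rod_modulus rod elastic modulus, GPa (cobalt-chrome, 213); the
#'   rod is treated as a rigid shaped curve during simulation, the modulus
#'   being orders of magnitude above the osteoligamentous stiffness.
#' @param screw_modulus screw modulus, GPa. Default 11 as printed in the
#'   source patient dataset; the usual titanium alloy value 110 is
#'   selectable. Moot mechanically: the screw-bone interface is rigid.
#' @param screw_length screw length, mm.
#' @param head_cone_half_angle polyaxial capture cone half angle, degrees
#'   (default 30, i.e. a 60 degree full cone).
#' @export
implant_spec <- function(rod_diameter = 5.5, rod_modulus = 213,
                         screw_modulus = 11, screw_length = 40,
                         head_cone_half_angle = 30) {
  stopifnot(rod_diameter > 0, screw_length > 0, head_cone_half_angle > 0)
  structure(list(rod_diameter = rod_diameter, rod_modulus = rod_modulus,
                 screw_modulus = screw_modulus, screw_length = screw_length,
                 head_cone_half_angle = head_cone_half_angle),
            class = "implant_spec")
}

#' Place pedicle screws on a spine model
#'
#' The default plan instruments the concave side of the main curve at
#' T3-T6 and T9-L1 (nine screws). Screw frames are rigid with their
#' vertebrae: the head centre sits lateral and posterior to the body
#' centroid at the pedicle entry, the axis pointing from the head into the
#' body.
#'
#' @param model a `spine_model`.
#' @param levels character vector of levels to instrument.
#' @param side `"concave"` or `"convex"` relative to the main curve.
#' @return list of screw elements.
#' @export
place_screws <- function(model,
                         levels = c("T3", "T4", "T5", "T6",
                                    "T9", "T10", "T11", "T12", "L1"),
                         side = "concave") {
  if (anyDuplicated(levels)) stop("duplicate screw placement")
  idx <- match(levels, spine_levels())
  if (anyNA(idx)) stop("level without a vertebra: ",
                       paste(levels[is.na(idx)], collapse = ", "))
  sgn <- if (side == "concave") model$concave_side else -model$concave_side
  lapply(seq_along(levels), function(k) {
    i <- idx[k]
    tab <- model$table
    r_head <- c(sgn * tab$pedicle_lateral[i],
                -(tab$body_depth[i] / 2 + tab$pedicle_posterior[i]), 0)
    ax_in <- -r_head / sqrt(sum(r_head^2))
    list(level = levels[k], body = i, side = side,
         r_head = r_head,                       # head centre, local frame
         axis_in_local = ax_in)                 # into the pedicle
  })
}

# Screw head centre and outward axis in the global frame of a state.
.screw_head <- function(state, screw) {
  R <- state$R[[screw$body]]
  list(p = state$p[[screw$body]] + as.vector(R %*% screw$r_head),
       axis_out = -as.vector(R %*% screw$axis_in_local))
}

#' Shape the spinal rod to a sagittal profile
#'
#' Builds a planar rod curve whose tangent-angle sweep equals the thoracic
#' kyphosis target over the thoracic span and the lordosis target (opposite
#' sign) over the lumbar span, using raised-cosine curvature bumps. The
#' curve lies in the rod's own sagittal plane and is straight in its own
#' coronal projection.
#'
#' @param kyphosis,lordosis sagittal targets, degrees.
#' @param length total rod arclength, mm.
#' @param thoracic_end arclength at which the thoracic span ends, mm.
#' @param spec an [implant_spec()].
#' @param ds sampling step for the stored polyline, mm.
#' @return object of class `rod_curve`: arclength stations `s`, local
#'   points `pts` (n x 3), local unit tangents `tans` (n x 3).
#' @export
shape_rod <- function(kyphosis, lordosis, length, thoracic_end,
                      spec = implant_spec(), ds = 1) {
  stopifnot(length > 0, thoracic_end > 0, thoracic_end <= length)
  s <- seq(0, length, by = ds)
  if (s[base::length(s)] < length) s <- c(s, length)
  # normalized cumulative raised-cosine bumps over each span
  bump_cdf <- function(s, s0, s1) {
    x <- pmin(pmax((s - s0) / (s1 - s0), 0), 1)
    x - sin(2 * pi * x) / (2 * pi)
  }
  phi <- deg2rad(kyphosis) * bump_cdf(s, 0, thoracic_end) -
    deg2rad(lordosis) * bump_cdf(s, thoracic_end, length)
  phi <- phi - deg2rad(kyphosis) / 2          # centre the heading
  # integrate heading d(phi) = (0, sin phi, -cos phi) with midpoint rule
  n <- base::length(s)
  pts <- matrix(0, n, 3)
  for (i in 2:n) {
    pm <- (phi[i - 1] + phi[i]) / 2
    pts[i, ] <- pts[i - 1, ] + (s[i] - s[i - 1]) * c(0, sin(pm), -cos(pm))
  }
  tans <- cbind(0, sin(phi), -cos(phi))
  structure(list(diameter = spec$rod_diameter, s = s, pts = pts, tans = tans,
                 phi = phi, length = length, thoracic_end = thoracic_end,
                 kyphosis = kyphosis, lordosis = lordosis),
            class = "rod_curve")
}

#' Tangent-angle sweep of a rod curve over an arclength interval
#' @param rod a `rod_curve`.
#' @param s0,s1 arclength interval, mm.
#' @return sweep in degrees.
#' @export
rod_sweep <- function(rod, s0 = 0, s1 = rod$length) {
  rad2deg(abs(stats::approx(rod$s, rod$phi, xout = s1)$y -
              stats::approx(rod$s, rod$phi, xout = s0)$y))
}

# Local rod point / tangent at arbitrary arclength.
.rod_at <- function(rod, s) {
  p <- vapply(1:3, function(j) stats::approx(rod$s, rod$pts[, j], xout = s)$y, 0)
  tg <- vapply(1:3, function(j) stats::approx(rod$s, rod$tans[, j], xout = s)$y, 0)
  list(p = p, tan = tg / sqrt(sum(tg^2)))
}

#' Instrument a spine model with screws, rod and linkages
#'
#' Places the screws, shapes the rod from the postoperative sagittal
#' targets with arclength stations at the screw-head chord distances, and
#' registers the rod onto the scoliotic screw-head line by rigid least
#' squares (the inserted rod therefore lies in the plane of the deformity
#' and is later derotated into the sagittal plane). One three-joint
#' linkage is created per screw, initially uncaptured.
#'
#' @param model a `spine_model`.
#' @param levels screw levels.
#' @param postop_kyphosis,postop_lordosis sagittal targets shaping the
#'   rod, degrees.
#' @param spec an [implant_spec()].
#' @param overhang rod overhang beyond the end screws, mm.
#' @param lumbar_sweep tangent sweep of the rod's short lumbar end, deg;
#'   by default the pro-rata arclength share of the lordosis target.
#' @return the model with `screws`, `rod` and `linkages` attached.
#' @export
instrument_spine <- function(model,
                             levels = c("T3", "T4", "T5", "T6",
                                        "T9", "T10", "T11", "T12", "L1"),
                             postop_kyphosis = 26, postop_lordosis = 36,
                             spec = implant_spec(), overhang = 10,
                             lumbar_sweep = NULL) {
  screws <- place_screws(model, levels)
  st <- as_built_state(model)
  heads <- t(vapply(screws, function(sc) .screw_head(st, sc)$p, numeric(3)))
  chord <- sqrt(rowSums((heads[-1, , drop = FALSE] -
                         heads[-nrow(heads), , drop = FALSE])^2))
  stations <- overhang + c(0, cumsum(chord))
  L <- stations[length(stations)] + overhang
  i_t12 <- match("T12", levels)
  th_end <- if (is.na(i_t12)) 0.8 * L else stations[i_t12]
  # the rod carries the lordosis angular rate over its short lumbar span,
  # not the whole L1-L5 lordosis: pro-rata share by arclength
  lumbar_len <- sum(model$heights[13:16])
  if (is.null(lumbar_sweep))
    lumbar_sweep <- postop_lordosis * (L - th_end) / lumbar_len
  rod <- shape_rod(postop_kyphosis, lumbar_sweep, L, th_end, spec)
  rod_pts <- t(vapply(stations, function(s) .rod_at(rod, s)$p, numeric(3)))
  reg <- kabsch(rod_pts, heads)
  pose <- list(R = reg$R, t = reg$t)
  # insert the rod with its bow lying in the coronal plane on the side of
  # the deformity (the rod is later derotated into the sagittal plane)
  pose <- .roll_bow_coronal(rod, pose, heads)
  rod$pose0 <- pose
  rod$stations <- stations
  model$implant <- spec
  model$screws <- screws
  model$rod <- rod
  model$linkages <- lapply(seq_along(screws), function(k) {
    at <- .rod_at(rod, stations[k])
    list(screw = k, station = stations[k],
         c_loc = at$p, tan_loc = at$tan, mode = "none",
         o_ramp = c(0, 0, 0), a_frozen = NULL)
  })
  model
}

# Roll the posed rod about its own chord so that its bow deflection lies
# in the coronal plane (global XZ), pointing to the same side as the bow
# of the screw-head line.
.roll_bow_coronal <- function(rod, pose, heads) {
  ends <- rod$pts[c(1, nrow(rod$pts)), ]
  mid <- .rod_at(rod, rod$length / 2)$p
  chord <- ends[2, ] - ends[1, ]
  chord <- chord / sqrt(sum(chord^2))
  bow_l <- (mid - ends[1, ]) - sum((mid - ends[1, ]) * chord) * chord
  axis_g <- as.vector(pose$R %*% chord)
  bow_g <- as.vector(pose$R %*% bow_l)
  # head-line bow, coronal component sign
  hchord <- heads[nrow(heads), ] - heads[1, ]
  hmid <- heads[ceiling(nrow(heads) / 2), ] - heads[1, ]
  hbow <- hmid - sum(hmid * hchord) / sum(hchord^2) * hchord
  side <- sign(hbow[1])
  if (side == 0) side <- 1
  # target bow direction: coronal (x) on the deformity side, orthogonal
  # to the rod axis
  tgt <- c(side, 0, 0) - axis_g[1] * side * axis_g
  nt <- sqrt(sum(tgt^2))
  if (nt < 1e-9) return(pose)
  tgt <- tgt / nt
  bperp <- bow_g - sum(bow_g * axis_g) * axis_g
  bperp <- bperp / sqrt(sum(bperp^2))
  cr <- c(bperp[2] * tgt[3] - bperp[3] * tgt[2],
          bperp[3] * tgt[1] - bperp[1] * tgt[3],
          bperp[1] * tgt[2] - bperp[2] * tgt[1])
  ang <- atan2(sum(cr * axis_g), sum(bperp * tgt))
  centre <- as.vector(pose$R %*% colMeans(rod$pts)) + pose$t
  Rd <- rot_exp(ang * axis_g)
  list(R = Rd %*% pose$R,
       t = as.vector(Rd %*% (pose$t - centre)) + centre)
}

#' Gap between a screw head and the rod
#'
#' Minimum distance from the screw head centre to the rod curve, by dense
#' arclength sampling of the posed rod polyline.
#'
#' @param sim a `spine_sim` context (or an instrumented `spine_model`).
#' @param k screw index.
#' @param state state to evaluate.
#' @return nonnegative distance, mm (0 when fully captured).
#' @export
linkage_gap <- function(sim, k, state = sim$state) {
  model <- if (inherits(sim, "spine_model")) sim else sim$model
  rod <- model$rod
  pose <- if (!is.null(state$rod)) state$rod else rod$pose0
  head <- .screw_head(state, model$screws[[k]])$p
  ss <- seq(0, rod$length, length.out = 2048)
  P <- t(vapply(1:3, function(j) stats::approx(rod$s, rod$pts[, j], xout = ss)$y,
                numeric(length(ss))))
  Pg <- pose$R %*% P + pose$t
  sqrt(min(colSums((Pg - head)^2)))
}

#' Polyaxial capture-cone check
#'
#' A rod is captured with the screw seated nominally when the rod tangent
#' is perpendicular to the screw axis; the polyaxial head tolerates a
#' deviation up to the cone half angle (30 degrees, inclusive at the
#' boundary).
#'
#' @param sim a `spine_sim` context (or instrumented `spine_model`).
#' @param k screw index.
#' @param state state to evaluate.
#' @return TRUE if the capture orientation lies within the cone.
#' @export
cone_check <- function(sim, k, state = sim$state) {
  model <- if (inherits(sim, "spine_model")) sim else sim$model
  pose <- if (!is.null(state$rod)) state$rod else model$rod$pose0
  lk <- if (!inherits(sim, "spine_model") && !is.null(sim$link))
    sim$link[[k]] else model$linkages[[k]]
  tg <- as.vector(pose$R %*% lk$tan_loc)
  ax <- .screw_head(state, model$screws[[k]])$axis_out
  ang <- rad2deg(acos(min(1, max(-1, abs(sum(tg * ax))))))
  deviation <- abs(90 - ang)
  deviation <= model$implant$head_cone_half_angle + 1e-9
}
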