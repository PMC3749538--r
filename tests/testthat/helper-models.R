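# Shared fixtures, built once per test run and cached.

.cache <- new.env(parent = emptyenv())

ref_profile <- function() patient_profile(73, 42, 35, 37, bending_cobb = 40)

ref_model <- function() {
  if (is.null(.cache$model)) .cache$model <- build_spine(ref_profile())
  .cache$model
}

straight_model <- function() {
  if (is.null(.cache$straight))
    .cache$straight <- build_spine(patient_profile(0, 0, 0, 0))
  .cache$straight
}

# Full reference pipeline (calibrate + instrument + ten-step surgery),
# run once and reused by the acceptance tests.
ref_pipeline <- function() {
  if (is.null(.cache$pipeline)) {
    cfg <- make_reference_case()
    model <- case_model(cfg, instrument = FALSE, calibrated = FALSE)
    cal <- calibrate_flexibility(model)
    model$discs <- create_discs(model, E_annulus = cal$E_annulus)
    model <- instrument_spine(model)
    t0 <- proc.time()[["elapsed"]]
    traj <- run_surgery(model)
    elapsed <- proc.time()[["elapsed"]] - t0
    .cache$pipeline <- list(model = model, cal = cal, traj = traj,
                            surgery_seconds = elapsed)
  }
  .cache$pipeline
}

# Synthetic single-disc element with prescribed section and height,
# connecting bodies ia and ib co-axially along +Z.
toy_disc <- function(area = 600, h = 10, ia = 1L, ib = 2L,
                     materials = material_library(E_annulus = 8, E_nucleus = 8)) {
  a <- sqrt(area / pi)
  list(upper = ia, lower = ib, upper_level = "T1", lower_level = "T2",
       a = a, b = a, area = area, height = h,
       nucleus_area_fraction = materials$nucleus_area_fraction,
       r_upper = c(0, 0, -h / 2), r_lower = c(0, 0, h / 2),
       delta_t0 = c(0, 0, 0), Qrel0 = diag(3),
       K = disc_stiffness(a, a, h, materials))
}

# Minimal state for two stacked rigid bodies h apart.
toy_state <- function(dz = 0, h = 10) {
  structure(list(R = list(diag(3), diag(3)),
                 p = list(c(0, 0, h + dz), c(0, 0, 0)),
                 rod = NULL, ref = diag(3)),
            class = "spine_state")
}

# Finite-difference gradient of the solver objective in scaled coords.
fd_gradient <- function(sim, q, map, h = 1e-6) {
  vapply(seq_along(q), function(i) {
    qp <- q; qp[i] <- qp[i] + h
    qm <- q; qm[i] <- qm[i] - h
    Ep <- spinesim:::.energy_grad(sim, spinesim:::.q_to_disp(sim, qp, map),
                                  want_grad = FALSE)$E
    Em <- spinesim:::.energy_grad(sim, spinesim:::.q_to_disp(sim, qm, map),
                                  want_grad = FALSE)$E
    (Ep - Em) / (2 * h)
  }, 0)
}

scaled_gradient <- function(sim, q, map) {
  U <- spinesim:::.q_to_disp(sim, q, map)
  G <- spinesim:::.energy_grad(sim, U)$G
  G[, 4:6] <- G[, 4:6] / spinesim:::ROT_SCALE
  G[map]
}

# Apply a common rigid motion to a state (reference frame co-rotates).
rigid_motion <- function(state, Rg, tg) {
  st <- state
  st$R <- lapply(state$R, function(R) Rg %*% R)
  st$p <- lapply(state$p, function(p) as.vector(Rg %*% p) + tg)
  if (!is.null(state$rod))
    st$rod <- list(R = Rg %*% state$rod$R,
                   t = as.vector(Rg %*% state$rod$t) + tg)
  st$ref <- Rg %*% (if (is.null(state$ref)) diag(3) else state$ref)
  st
}
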