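test_that("the unloaded as-built model is already at equilibrium", {
  sim <- spine_sim(ref_model())
  expect_equal(total_energy(sim), 0)
  sim2 <- solve_equilibrium(sim)
  expect_equal(sim2$energy, 0, tolerance = 1e-9)
  for (i in 1:17) {
    expect_equal(sim2$state$p[[i]], sim$state$p[[i]], tolerance = 1e-6)
    expect_equal(sim2$state$R[[i]], sim$state$R[[i]], tolerance = 1e-8)
  }
})

test_that("analytic gradient matches finite differences on random states", {
  m <- instrument_spine(ref_model())
  sim <- spine_sim(m)
  lev <- vapply(m$screws, `[[`, "", "level")
  sim$link[[match("T3", lev)]]$mode <- "slide_axial"
  sim$link[[match("L1", lev)]]$mode <- "point"
  map <- spinesim:::.dof_map(sim)
  set.seed(31)
  for (r in 1:3) {
    q <- rnorm(nrow(map)) * 0.3
    g <- scaled_gradient(sim, q, map)
    gfd <- fd_gradient(sim, q, map)
    expect_lt(max(abs(g - gfd)) / max(abs(gfd)), 1e-5)
  }
})

test_that("axial load compresses each disc by the closed-form F/k", {
  # a sub-critical axial load on the straight chain (the unsupported
  # osteoligamentous column buckles near ~15 N, so a small load is used
  # to probe the series-spring behaviour) shortens every disc by F/k
  m <- straight_model()
  sim <- spine_sim(m)
  F <- 4
  sim$ext <- list(body = 1L, comp = 3L, M = -F)   # downward force on T1
  sim <- solve_equilibrium(sim)
  for (j in c(1, 8, 16)) {
    d <- m$discs[[j]]
    comp <- spinesim:::.disc_delta(sim$state, d)$delta[3]
    expect_equal(comp, -F / d$K[3, 3], tolerance = 1e-3)
  }
  # the closed form at the example stiffness: 100 N on 480 N/mm
  expect_equal(100 / 480, 0.2083, tolerance = 1e-3)
})

test_that("equilibrium matches a dense linear solve in the small-load regime", {
  # linearize about a lightly pre-loaded state (the unloaded rest state
  # sits exactly on the tension-only kink of every ligament, where no
  # tangent stiffness is defined), then compare the equilibrium under a
  # small load increment with the dense solve of the assembled system
  m <- straight_model()
  sim <- spine_sim(m)
  sim$ext <- list(body = 8L, comp = 1L, M = 0.5)
  sim <- solve_equilibrium(sim, tol = 1e-8)
  map <- spinesim:::.dof_map(sim)
  n <- nrow(map)
  H <- matrix(0, n, n)
  h <- 1e-6
  g0 <- scaled_gradient(sim, numeric(n), map)
  for (i in 1:n) {
    qp <- numeric(n); qp[i] <- h
    H[, i] <- (scaled_gradient(sim, qp, map) - g0) / h
  }
  H <- (H + t(H)) / 2
  df <- 0.01                       # small force increment
  i8 <- which(map[, 1] == 8 & map[, 2] == 1)
  f <- numeric(n); f[i8] <- df
  q_lin <- solve(H, f)
  p0 <- sim$state$p[[8]]
  sim$ext$M <- 0.5 + df
  sim2 <- solve_equilibrium(sim, tol = 1e-9)
  du <- sim2$state$p[[8]][1] - p0[1]
  expect_equal(du, q_lin[i8], tolerance = 1e-6)
})

test_that("equilibrium is independent of the starting perturbation", {
  m <- straight_model()
  sim <- spine_sim(m)
  sim$ext <- list(body = 1L, comp = 1L, M = 20)
  a <- solve_equilibrium(sim)
  # perturb the start state and re-solve
  simp <- sim
  set.seed(32)
  for (i in 2:16) simp$state$p[[i]] <- simp$state$p[[i]] + rnorm(3) * 0.5
  b <- solve_equilibrium(simp)
  for (i in 1:17)
    expect_equal(b$state$p[[i]], a$state$p[[i]], tolerance = 1e-4)
})

test_that("empty surgical plan returns only the initial state", {
  traj <- run_surgery(instrument_spine(ref_model()), plan = list())
  expect_length(traj$steps, 0)
  expect_equal(traj$initial$measures$angles[["main_cobb"]],
               ref_model()$as_built_measures[["main"]], tolerance = 1e-9)
})

test_that("re-reducing an already captured screw changes nothing", {
  m <- instrument_spine(ref_model())
  sim <- spine_sim(m)
  out <- run_step(sim, list(label = "1", kind = "capture_ends"))
  sim <- out$sim
  lev <- vapply(m$screws, `[[`, "", "level")
  kL1 <- match("L1", lev)
  st0 <- sim$state
  sim2 <- spinesim:::.capture_ramp(sim, kL1, "point", substeps = 3,
                                   label = "again")
  for (i in 1:17)
    expect_equal(sim2$state$p[[i]], st0$p[[i]], tolerance = 1e-2)
})

test_that("flexibility calibration recovers a known annulus modulus", {
  m <- ref_model()
  for (E_true in c(5, 9)) {
    m2 <- m
    m2$discs <- create_discs(m2, E_annulus = E_true)
    target <- lateral_bending_test(m2)
    prof <- ref_profile()
    prof$bending_cobb <- target
    cal <- calibrate_flexibility(m, profile = prof)
    expect_lt(abs(cal$E_annulus - E_true) / E_true, 0.02)
  }
})

test_that("degenerate bending targets are rejected", {
  m <- ref_model()
  prof <- ref_profile()
  prof$bending_cobb <- prof$main_thoracic_cobb     # no correction demanded
  expect_error(calibrate_flexibility(m, profile = prof), "degenerate")
  prof$bending_cobb <- 72.9
  expect_error(calibrate_flexibility(m, profile = prof), "unreachable")
})

test_that("lateral bending simulations are bit-deterministic", {
  m <- ref_model()
  a <- lateral_bending_test(m)
  b <- lateral_bending_test(m)
  expect_identical(a, b)
})
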