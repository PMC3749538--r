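arc_state <- function(n_wedges, theta_deg, axis = "y") {
  R <- vector("list", 17)
  R[[1]] <- diag(3)
  for (i in 2:17) {
    a <- spinesim:::deg2rad(theta_deg) * min(i - 1, n_wedges)
    R[[i]] <- if (axis == "y") rot_y(a) else rot_x(a)
  }
  structure(list(R = R, p = rep(list(c(0, 0, 0)), 17), rod = NULL,
                 ref = diag(3)), class = "spine_state")
}

test_that("Cobb angle composes over a circular-arc chain", {
  expect_equal(as.numeric(cobb_angle(arc_state(16, 0), "T1", "L5", "coronal")), 0)
  # ten equal 5-degree coronal wedges end to end measure 50 degrees
  st <- arc_state(10, 5)
  expect_equal(as.numeric(cobb_angle(st, "T1", "T11", "coronal")), 50,
               tolerance = 1e-9)
  # composition oracle: arbitrary spans equal the wedge sums between them
  expect_equal(as.numeric(cobb_angle(st, "T3", "T8", "coronal")), 25,
               tolerance = 1e-9)
})

test_that("plane projections do not cross-talk for single-plane deformities", {
  sag <- arc_state(10, 4, axis = "x")
  expect_equal(as.numeric(cobb_angle(sag, "T1", "T11", "coronal")), 0,
               tolerance = 1e-9)
  cor <- arc_state(10, 4, axis = "y")
  expect_equal(as.numeric(cobb_angle(cor, "T1", "T11", "sagittal")), 0,
               tolerance = 1e-9)
})

test_that("Cobb measures are invariant under a global rigid motion", {
  m <- ref_model()
  st <- as_built_state(m)
  st2 <- rigid_motion(st, rot_exp(c(0.7, -0.3, 1.1)), c(100, -40, 20))
  for (lv in list(c("T6", "T12", "coronal"), c("T1", "T12", "sagittal"),
                  c("L1", "L5", "sagittal"))) {
    expect_equal(as.numeric(cobb_angle(st2, lv[1], lv[2], lv[3])),
                 as.numeric(cobb_angle(st, lv[1], lv[2], lv[3])),
                 tolerance = 1e-9)
  }
})

test_that("cobb_angle validates its inputs", {
  st <- as_built_state(ref_model())
  expect_error(cobb_angle(st, "T5", "T5", "coronal"), "cranial")
  expect_error(cobb_angle(st, "T12", "T6", "coronal"), "cranial")
  expect_error(cobb_angle(st, "T99", "L5", "coronal"), "level")
})

test_that("as-built measures report zero loads", {
  m <- instrument_spine(ref_model())
  sim <- spine_sim(m)
  ms <- per_step_measures(sim)
  expect_equal(max(ms$disc_stress), 0)
  expect_equal(max(abs(ms$pullout[, "pullout"])), 0)
  expect_equal(nrow(ms$pullout), 9)
})

test_that("empty trajectories yield a not-evaluated report", {
  traj <- run_surgery(instrument_spine(ref_model()), plan = list())
  rep <- validation_report(traj)
  expect_false(rep$evaluated)
  expect_match(unname(rep$criteria["pullout"]), "not evaluated")
})

test_that("an injected excessive pullout force fails the report", {
  p <- ref_pipeline()
  traj <- p$traj
  n <- length(traj$steps)
  traj$steps[[n]]$measures$pullout[1, "pullout"] <- 2500
  rep <- validation_report(traj)
  expect_false(rep$pullout_pass)
  rep0 <- validation_report(p$traj)
  expect_true(rep0$pullout_pass)
})

test_that("the validation report is byte-identical across evaluations", {
  p <- ref_pipeline()
  a <- capture.output(print(validation_report(p$traj)))
  b <- capture.output(print(validation_report(p$traj)))
  expect_identical(a, b)
})
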