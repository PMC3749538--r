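test_that("the default plan places nine concave-side screws", {
  m <- ref_model()
  sc <- place_screws(m)
  expect_length(sc, 9)
  expect_equal(vapply(sc, `[[`, "", "level"),
               c("T3", "T4", "T5", "T6", "T9", "T10", "T11", "T12", "L1"))
  expect_length(place_screws(m, character(0)), 0)
  expect_error(place_screws(m, c("T3", "T3")), "duplicate")
  expect_error(place_screws(m, "T13"), "level")
})

test_that("screw heads move rigidly with their vertebrae", {
  m <- ref_model()
  sc <- place_screws(m)[[4]]
  st <- as_built_state(m)
  h0 <- spinesim:::.screw_head(st, sc)$p
  Rg <- rot_exp(c(0.2, 0.4, -0.3)); tg <- c(5, -8, 12)
  st2 <- st
  i <- sc$body
  st2$R[[i]] <- Rg %*% st$R[[i]]
  st2$p[[i]] <- as.vector(Rg %*% st$p[[i]]) + tg
  h1 <- spinesim:::.screw_head(st2, sc)$p
  expect_equal(h1, as.vector(Rg %*% h0) + tg, tolerance = 1e-10)
})

test_that("rod shaping hits the requested tangent sweeps", {
  r0 <- shape_rod(0, 0, 300, 240)
  expect_lt(rod_sweep(r0), 1e-9)
  expect_lt(max(abs(r0$pts[, 1])), 1e-12)    # planar
  r <- shape_rod(26, 36, 300, 240)
  expect_equal(rod_sweep(r, 0, 240), 26, tolerance = 0.5)
  expect_equal(rod_sweep(r, 240, 300), 36, tolerance = 0.5)
  # total signed sweep equals the sum of the segment sweeps
  sweep_total <- spinesim:::rad2deg(abs(r$phi[length(r$phi)] - r$phi[1]))
  expect_equal(sweep_total, abs(26 - 36), tolerance = 0.5)
})

test_that("initial linkage gaps match a brute-force nearest-distance search", {
  m <- instrument_spine(ref_model())
  st <- as_built_state(m)
  for (k in c(1, 5, 9)) {
    gap <- linkage_gap(m, k, st)
    head <- spinesim:::.screw_head(st, m$screws[[k]])$p
    ss <- seq(0, m$rod$length, length.out = 1e4)
    pose <- m$rod$pose0
    dmin <- sqrt(min(vapply(ss, function(s) {
      p <- as.vector(pose$R %*% spinesim:::.rod_at(m$rod, s)$p) + pose$t
      sum((p - head)^2)
    }, 0)))
    expect_equal(gap, dmin, tolerance = 1e-3)
  }
})

test_that("gap and cone angle are invariant under a common rigid motion", {
  m <- instrument_spine(ref_model())
  st <- as_built_state(m)
  st2 <- rigid_motion(st, rot_exp(c(0.5, -0.2, 0.8)), c(30, -10, 50))
  for (k in seq_along(m$screws)) {
    expect_equal(linkage_gap(m, k, st2), linkage_gap(m, k, st),
                 tolerance = 1e-9)
    expect_equal(cone_check(m, k, st2), cone_check(m, k, st))
  }
})

test_that("the polyaxial capture cone is inclusive at its 30-degree boundary", {
  m <- instrument_spine(ref_model())
  st <- as_built_state(m)
  k <- 4
  sc <- m$screws[[k]]
  pose <- m$rod$pose0
  tg <- as.vector(pose$R %*% m$linkages[[k]]$tan_loc)
  ax <- spinesim:::.screw_head(st, sc)$axis_out
  # rotate the screw's vertebra so the axis-tangent deviation is exact
  n <- c(tg[2] * ax[3] - tg[3] * ax[2], tg[3] * ax[1] - tg[1] * ax[3],
         tg[1] * ax[2] - tg[2] * ax[1])
  n <- n / sqrt(sum(n^2))
  dev_of <- function(s) {
    ax2 <- spinesim:::.screw_head(s, sc)$axis_out
    90 - spinesim:::rad2deg(acos(min(1, abs(sum(tg * ax2)))))
  }
  dev0 <- dev_of(st)
  set_deviation <- function(dev_deg) {
    rot <- spinesim:::deg2rad(dev_deg - dev0)
    cand <- lapply(c(rot, -rot), function(r) {
      st2 <- st
      st2$R[[sc$body]] <- rot_exp(r * n) %*% st$R[[sc$body]]
      st2
    })
    errs <- vapply(cand, function(s) abs(dev_of(s) - dev_deg), 0)
    s <- cand[[which.min(errs)]]
    stopifnot(abs(dev_of(s) - dev_deg) < 1e-6)
    s
  }
  expect_true(cone_check(m, k, set_deviation(0)))
  expect_true(cone_check(m, k, set_deviation(29)))
  expect_true(cone_check(m, k, set_deviation(30)))   # inclusive boundary
  expect_false(cone_check(m, k, set_deviation(31)))
})
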