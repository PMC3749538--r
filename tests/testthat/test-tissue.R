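test_that("disc stiffness follows the composite beam formulas", {
  mats8 <- material_library(E_annulus = 8, E_nucleus = 8)
  a <- sqrt(600 / pi)
  K <- disc_stiffness(a, a, 10, mats8)
  expect_equal(K[3, 3], 8 * 600 / 10, tolerance = 1e-9)     # axial EA/h
  # doubling the height halves every entry
  K2 <- disc_stiffness(a, a, 20, mats8)
  expect_equal(unname(diag(K2)), unname(diag(K)) / 2, tolerance = 1e-12)
  # area-weighted composite modulus: 0.6*8 + 0.4*2 = 5.6
  mats <- material_library(E_annulus = 8, E_nucleus = 2,
                           nucleus_area_fraction = 0.4)
  K3 <- disc_stiffness(a, a, 10, mats)
  expect_equal(K3[3, 3], 5.6 * 600 / 10, tolerance = 1e-9)
  # shear uses G = E/(2(1+nu))
  G <- 5.6 / (2 * (1 + mats$poisson_disc))
  expect_equal(K3[1, 1], G * 600 / 10, tolerance = 1e-9)
  expect_error(disc_stiffness(a, a, 0, mats), "degenerate")
})

test_that("every model disc stiffness matrix is symmetric positive definite", {
  for (d in ref_model()$discs) {
    expect_equal(d$K, t(d$K))
    expect_no_error(chol(d$K))
  }
})

test_that("ligament force is linear in tension and zero in slack", {
  ligs <- create_ligaments(ref_model())
  all_ <- ligs[[which(vapply(ligs, `[[`, "", "type") == "ALL")[1]]]
  isl <- ligs[[which(vapply(ligs, `[[`, "", "type") == "ISL")[1]]]
  expect_equal(ligament_force(all_, all_$rest_length + 1), 23.75)
  expect_equal(ligament_force(isl, isl$rest_length + 2.5), 9.8 * 2.5)
  expect_equal(ligament_force(all_, all_$rest_length), 0)
  expect_equal(ligament_force(all_, all_$rest_length * 0.5), 0)
})

test_that("the full model carries 96 tension-only ligaments at zero prestrain", {
  m <- ref_model()
  ligs <- m$ligaments
  expect_length(ligs, 96)
  expect_equal(sum(vapply(ligs, `[[`, "", "type") == "CAP"), 32) # bilateral
  st <- as_built_state(m)
  f <- vapply(ligs, function(l)
    ligament_force(l, spinesim:::.lig_length(st, l)), 0)
  expect_equal(max(abs(f)), 0)
})

test_that("disc wrench is linear, frame-consistent and zero at rest", {
  d <- toy_disc()
  expect_equal(disc_wrench(toy_state(0), d), rep(0, 6))
  w <- disc_wrench(toy_state(-1), d)      # 1 mm axial compression
  expect_equal(w[3], -480, tolerance = 1e-9)
  expect_equal(w[-3], rep(0, 5), tolerance = 1e-9)
})

test_that("energy equals stored elastic energy for an imposed displacement", {
  d <- toy_disc()
  st <- toy_state(-1)
  delta <- spinesim:::.disc_delta(st, d)$delta
  E <- 0.5 * sum(delta * (d$K %*% delta))
  expect_equal(E, 0.5 * 480 * 1, tolerance = 1e-9)   # 240 N.mm
})

test_that("stress recovery reduces to F/A under pure axial load", {
  d <- toy_disc()
  s <- disc_stress(toy_state(-1), d)
  expect_equal(s, 480 / 600, tolerance = 1e-9)       # 0.8 MPa
})

test_that("both disc moduli assignments are selectable", {
  m1 <- material_library()
  m2 <- material_library(swap_moduli = TRUE)
  expect_equal(m1$E_annulus, 8)
  expect_equal(m2$E_annulus, 2)
  expect_equal(m2$E_nucleus, 8)
})
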