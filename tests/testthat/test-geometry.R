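test_that("rotation exponential and logarithm are mutual inverses", {
  set.seed(11)
  for (i in 1:50) {
    q <- rnorm(3) * runif(1, 0, 3)  # angles up to ~3 rad
    R <- rot_exp(q)
    expect_equal(crossprod(R), diag(3), tolerance = 1e-12)
    expect_equal(det(R), 1, tolerance = 1e-12)
    q2 <- rot_log(R)
    expect_equal(rot_exp(q2), R, tolerance = 1e-9)
  }
})

test_that("left Jacobian gives the derivative of the exponential map", {
  set.seed(12)
  h <- 1e-7
  for (i in 1:10) {
    q <- rnorm(3)
    J <- so3_jacl(q)
    for (k in 1:3) {
      dq <- numeric(3); dq[k] <- h
      dR <- (rot_exp(q + dq) - rot_exp(q - dq)) / (2 * h)
      W <- dR %*% t(rot_exp(q))            # should be skew(J e_k)
      gk <- c(W[3, 2], W[1, 3], W[2, 1])
      expect_equal(gk, as.vector(J[, k]), tolerance = 1e-6)
    }
    expect_equal(so3_jacl_inv(q) %*% J, diag(3), tolerance = 1e-9)
  }
})

test_that("rigid registration recovers a known transform", {
  set.seed(13)
  X <- matrix(rnorm(30), 10, 3)
  Rg <- rot_exp(c(0.3, -0.5, 0.9))
  tg <- c(4, -2, 7)
  Y <- t(Rg %*% t(X)) + rep(tg, each = 10)
  fit <- spinesim:::kabsch(X, Y)
  expect_equal(fit$R, Rg, tolerance = 1e-10)
  expect_equal(fit$t, tg, tolerance = 1e-10)
})

test_that("compiled energy kernel agrees with the pure-R reference", {
  model <- ref_model()
  model <- instrument_spine(model)
  sim <- spine_sim(model)
  lev <- vapply(model$screws, `[[`, "", "level")
  sim$link[[match("T3", lev)]]$mode <- "slide_axial"
  sim$link[[match("L1", lev)]]$mode <- "point"
  sim$link[[match("T5", lev)]]$mode <- "point"
  sim$link[[match("T5", lev)]]$Qlock <- diag(3)
  sim$ext <- list(body = 1L, comp = 5L, M = 3000)
  map <- spinesim:::.dof_map(sim)
  set.seed(14)
  for (r in 1:5) {
    q <- rnorm(nrow(map)) * 0.4
    U <- spinesim:::.q_to_disp(sim, q, map)
    a <- spinesim:::.energy_grad_r(sim, U)
    b <- spinesim:::.energy_grad(sim, U)
    expect_equal(b$E, a$E, tolerance = 1e-12)
    expect_equal(b$G, a$G, tolerance = 1e-12)
  }
})
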