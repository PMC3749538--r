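# Quasi-static equilibrium solver and the staged surgical simulation.
#
# The generalized coordinates of one solve are incremental rigid-body
# displacements from the state at solve start: per body a translation u
# (mm) and a rotation vector theta (radians) composed on the left,
# R = exp([theta]x) R_start. Rotational coordinates are scaled by
# ROT_SCALE mm internally so that translational and rotational stiffnesses
# are comparable and a single gradient tolerance applies.

ROT_SCALE <- 30

# Free component masks: T1 transversely constrained (tx, ty locked), L5
# fixed except coronal rotation (about global Y). Locked DOFs are
# eliminated from the coordinate vector, not penalized.
.free_comps <- function(i) {
  if (i == 1L) return(c(3L, 4L, 5L, 6L))
  if (i == 17L) return(5L)
  1:6
}

# DOF map rows: body (1..17, 18 = rod), comp (1..6: ux uy uz rx ry rz).
.dof_map <- function(sim) {
  rows <- do.call(rbind, lapply(1:17, function(i)
    cbind(body = i, comp = .free_comps(i))))
  if (!is.null(sim$model$rod) && sim$rod_free)
    rows <- rbind(rows, cbind(body = 18L, comp = 1:6))
  rows
}

# Unpack q into a full 18 x 6 displacement matrix (locked entries zero).
.q_to_disp <- function(sim, q, map) {
  U <- matrix(0, 18, 6)
  U[map] <- q
  U[, 4:6] <- U[, 4:6] / ROT_SCALE
  U
}

.apply_disp <- function(sim, U) {
  st <- sim$state
  R <- vector("list", 17); p <- vector("list", 17)
  for (i in 1:17) {
    th <- U[i, 4:6]
    R[[i]] <- if (all(th == 0)) st$R[[i]] else rot_exp(th) %*% st$R[[i]]
    p[[i]] <- st$p[[i]] + U[i, 1:3]
  }
  rod <- st$rod
  if (!is.null(rod) && sim$rod_free) {
    th <- U[18, 4:6]
    rod <- list(R = if (all(th == 0)) rod$R else rot_exp(th) %*% rod$R,
                t = rod$t + U[18, 1:3])
  }
  structure(list(R = R, p = p, rod = rod, ref = st$ref),
            class = "spine_state")
}

# Elastic + external potential and its gradient at displacement U.
# Returns list(E, G) with G an 18 x 6 matrix (unscaled physical units:
# N for translations, N.mm for rotations). Global torques are
# accumulated per body and mapped to rotation-vector coordinates through
# the transposed left Jacobian at the end. The compiled kernel does the
# work; .energy_grad_r is the pure-R reference used as an independent
# cross-check in the tests.
.energy_grad <- function(sim, U, want_grad = TRUE, pack = NULL) {
  if (is.null(pack)) pack <- .make_pack(sim)
  .energy_grad_cpp(pack, U, want_grad)
}

# Static (per-solve) element data marshalled for the compiled kernel.
.make_pack <- function(sim) {
  model <- sim$model
  st <- sim$state
  has_rod <- !is.null(model$rod)
  rodpose <- if (!is.null(st$rod)) st$rod
             else if (has_rod) model$rod$pose0
             else list(R = diag(3), t = c(0, 0, 0))
  discs <- model$discs
  la <- model$ligA
  link <- sim$link
  mode_code <- c(none = 0L, point = 1L, slide_axial = 2L,
                 slide_tangent = 3L, derot = 4L)
  nk <- length(link)
  get3 <- function(lst, f) {
    if (length(lst) == 0) return(matrix(0, 0, 3))
    t(vapply(lst, f, numeric(3)))
  }
  avec <- get3(link, function(l) {
    if (!is.null(l$a_frozen)) l$a_frozen
    else if (!is.null(l$cdir)) l$cdir else c(0, 0, 0)
  })
  Qlock <- if (nk == 0) matrix(0, 0, 9) else
    t(vapply(link, function(l)
      if (is.null(l$Qlock)) numeric(9) else as.vector(l$Qlock), numeric(9)))
  ext <- sim$ext
  list(
    Rstart = t(vapply(st$R, as.vector, numeric(9))),
    pstart = t(vapply(st$p, identity, numeric(3))),
    has_rod = as.integer(has_rod),
    rod_free = as.integer(isTRUE(sim$rod_free)),
    rodR = as.vector(rodpose$R), rodt = rodpose$t,
    disc_ia = vapply(discs, function(d) as.integer(d$upper), 0L),
    disc_ib = vapply(discs, function(d) as.integer(d$lower), 0L),
    disc_rup = get3(discs, function(d) d$r_upper),
    disc_rlo = get3(discs, function(d) d$r_lower),
    disc_dt0 = get3(discs, function(d) d$delta_t0),
    disc_Q0 = t(vapply(discs, function(d) as.vector(d$Qrel0), numeric(9))),
    disc_K = t(vapply(discs, function(d) diag(d$K), numeric(6))),
    lig_iu = la$iu, lig_il = la$il,
    lig_rup = la$r_up, lig_rlo = la$r_lo,
    lig_k = la$k, lig_L0 = la$L0,
    link_mode = if (nk == 0) integer(0) else
      unname(mode_code[vapply(link, `[[`, "", "mode")]),
    link_iv = if (nk == 0) integer(0) else
      vapply(link, function(l) as.integer(model$screws[[l$screw]]$body), 0L),
    link_rhead = get3(link, function(l) model$screws[[l$screw]]$r_head),
    link_target = get3(link, function(l) l$c_loc + l$o_ramp),
    link_avec = avec,
    link_hasQ = if (nk == 0) integer(0) else
      vapply(link, function(l) as.integer(!is.null(l$Qlock)), 0L),
    link_Qlock = Qlock,
    penalty_k = sim$penalty_k, penalty_rot = sim$penalty_rot,
    tether_k = sim$tether_k,
    ext_M = if (is.null(ext)) 0 else ext$M,
    ext_body = if (is.null(ext)) 1L else as.integer(ext$body),
    ext_comp = if (is.null(ext)) 1L else as.integer(ext$comp)
  )
}

.energy_grad_r <- function(sim, U, want_grad = TRUE) {
  model <- sim$model
  state <- .apply_disp(sim, U)
  E <- 0
  G <- if (want_grad) matrix(0, 18, 6) else NULL
  TQ <- if (want_grad) matrix(0, 18, 3) else NULL   # global torques
  Pmat <- do.call(rbind, state$p)

  # discs
  for (disc in model$discs) {
    d <- .disc_delta(state, disc)
    W <- as.vector(disc$K %*% d$delta)
    E <- E + 0.5 * sum(W * d$delta)
    if (want_grad) {
      C <- d$C
      Fg <- as.vector(C %*% W[1:3])
      Mg <- as.vector(C %*% (t(so3_jacl_inv(d$dr)) %*% W[4:6]))
      ia <- disc$upper; ib <- disc$lower
      G[ia, 1:3] <- G[ia, 1:3] + Fg
      G[ib, 1:3] <- G[ib, 1:3] - Fg
      aa <- d$o_up - state$p[[ia]]
      ab <- d$o_up - state$p[[ib]]
      TQ[ia, ] <- TQ[ia, ] +
        c(aa[2] * Fg[3] - aa[3] * Fg[2], aa[3] * Fg[1] - aa[1] * Fg[3],
          aa[1] * Fg[2] - aa[2] * Fg[1]) + Mg
      TQ[ib, ] <- TQ[ib, ] -
        c(ab[2] * Fg[3] - ab[3] * Fg[2], ab[3] * Fg[1] - ab[1] * Fg[3],
          ab[1] * Fg[2] - ab[2] * Fg[1]) - Mg
    }
  }

  # tension-only ligaments (vectorized over the 96 elements)
  la <- model$ligA
  if (!is.null(la)) {
    AU <- matrix(0, length(la$iu), 3); AL <- AU
    for (i in unique(la$iu)) {
      s <- la$iu == i
      AU[s, ] <- la$r_up[s, , drop = FALSE] %*% t(state$R[[i]])
    }
    for (i in unique(la$il)) {
      s <- la$il == i
      AL[s, ] <- la$r_lo[s, , drop = FALSE] %*% t(state$R[[i]])
    }
    PA <- Pmat[la$iu, , drop = FALSE] + AU
    PB <- Pmat[la$il, , drop = FALSE] + AL
    dv <- PA - PB
    L <- sqrt(rowSums(dv * dv))
    ext <- L - la$L0
    act <- ext > 0
    if (any(act)) {
      E <- E + 0.5 * sum(la$k[act] * ext[act]^2)
      if (want_grad) {
        Fm <- (la$k * pmax(ext, 0) / L) * dv         # force on upper attach
        Fm[!act, ] <- 0
        tqa <- cbind(AU[, 2] * Fm[, 3] - AU[, 3] * Fm[, 2],
                     AU[, 3] * Fm[, 1] - AU[, 1] * Fm[, 3],
                     AU[, 1] * Fm[, 2] - AU[, 2] * Fm[, 1])
        tqb <- cbind(AL[, 2] * Fm[, 3] - AL[, 3] * Fm[, 2],
                     AL[, 3] * Fm[, 1] - AL[, 1] * Fm[, 3],
                     AL[, 1] * Fm[, 2] - AL[, 2] * Fm[, 1])
        gF <- rowsum(rbind(Fm, -Fm), c(la$iu, la$il))
        idx <- as.integer(rownames(gF))
        G[idx, 1:3] <- G[idx, 1:3] + gF
        gT <- rowsum(rbind(tqa, -tqb), c(la$iu, la$il))
        TQ[idx, ] <- TQ[idx, ] + gT
      }
    }
  }

  # screw-rod linkage penalties
  if (!is.null(model$linkages)) {
    rodpose <- if (!is.null(state$rod)) state$rod else model$rod$pose0
    kpen <- sim$penalty_k
    for (lk in sim$link) {
      if (lk$mode == "none") next
      sc <- model$screws[[lk$screw]]
      iv <- sc$body
      armv <- as.vector(state$R[[iv]] %*% sc$r_head)
      ph <- state$p[[iv]] + armv
      xt <- as.vector(rodpose$R %*% (lk$c_loc + lk$o_ramp)) + rodpose$t
      dvec <- ph - xt
      Pd <- switch(lk$mode,
        point = dvec,
        slide_axial = c(dvec[1], dvec[2], 0),
        slide_tangent = dvec - sum(dvec * lk$a_frozen) * lk$a_frozen,
        derot = sum(dvec * lk$cdir) * lk$cdir)
      # fully tightened set screws also clamp the screw-rod relative
      # orientation (rotational bushing)
      if (!is.null(lk$Qlock)) {
        D <- crossprod(rodpose$R, state$R[[iv]]) %*% t(lk$Qlock)
        dr <- rot_log(D)
        kr <- sim$penalty_rot
        E <- E + 0.5 * kr * sum(dr * dr)
        if (want_grad) {
          Mg <- as.vector(rodpose$R %*% (t(so3_jacl_inv(dr)) %*% (kr * dr)))
          TQ[iv, ] <- TQ[iv, ] + Mg
          if (sim$rod_free) TQ[18, ] <- TQ[18, ] - Mg
        }
      }
      E <- E + 0.5 * kpen * sum(Pd * Pd)
      if (want_grad) {
        Fg <- kpen * Pd
        G[iv, 1:3] <- G[iv, 1:3] + Fg
        TQ[iv, ] <- TQ[iv, ] +
          c(armv[2] * Fg[3] - armv[3] * Fg[2],
            armv[3] * Fg[1] - armv[1] * Fg[3],
            armv[1] * Fg[2] - armv[2] * Fg[1])
        if (sim$rod_free) {
          armr <- xt - rodpose$t
          G[18, 1:3] <- G[18, 1:3] - Fg
          TQ[18, ] <- TQ[18, ] -
            c(armr[2] * Fg[3] - armr[3] * Fg[2],
              armr[3] * Fg[1] - armr[1] * Fg[3],
              armr[1] * Fg[2] - armr[2] * Fg[1])
        }
      }
    }
    # rod holder ("surgeon's grip"): a 6-DOF spring recentred at every
    # solve start; it regularizes the rod modes left free by partial
    # capture, and carries no force at a settled equilibrium because the
    # outer loop re-solves until the rod stops moving
    if (sim$rod_free) {
      kt <- sim$tether_k
      E <- E + 0.5 * kt[1] * sum(U[18, 1:3]^2) + 0.5 * kt[2] * sum(U[18, 4:6]^2)
      if (want_grad) G[18, 1:3] <- G[18, 1:3] + kt[1] * U[18, 1:3]
    }
  }

  if (want_grad) {
    for (i in 1:18) {
      if (any(TQ[i, ] != 0))
        G[i, 4:6] <- G[i, 4:6] +
          as.vector(crossprod(so3_jacl(U[i, 4:6]), TQ[i, ]))
    }
    # coordinate-level terms added after the Jacobian map
    if (!is.null(model$linkages) && sim$rod_free)
      G[18, 4:6] <- G[18, 4:6] + sim$tether_k[2] * U[18, 4:6]
  }

  # external generalized moment (lateral bending load case)
  if (!is.null(sim$ext)) {
    E <- E - sim$ext$M * U[sim$ext$body, sim$ext$comp]
    if (want_grad)
      G[sim$ext$body, sim$ext$comp] <- G[sim$ext$body, sim$ext$comp] - sim$ext$M
  }

  list(E = E, G = G, state = state)
}

#' Create a quasi-static simulation context
#'
#' @param model a built (optionally instrumented) `spine_model`.
#' @param penalty_k translational penalty stiffness of locked linkage
#'   directions, N/mm (the "stiff bushing" device; default 1e4).
#' @param tol gradient-infinity-norm convergence tolerance in scaled
#'   coordinates (N; rotational entries are moments divided by the 30 mm
#'   internal scale), default 1e-3.
#' @return object of class `spine_sim`.
#' @export
spine_sim <- function(model, penalty_k = 1e4, tol = 1e-3) {
  link <- model$linkages
  structure(list(model = model,
                 state = as_built_state(model),
                 link = if (is.null(link)) list() else link,
                 rod_free = !is.null(model$rod),
                 penalty_k = penalty_k,
                 penalty_rot = 1e5,
                 tether_k = c(10, 1e4),
                 ext = NULL, tol = tol),
            class = "spine_sim")
}

#' Total elastic potential energy of a state
#'
#' Sum of disc strain energy, tension-only ligament energy and linkage
#' penalty energy; zero at the as-built unloaded state.
#'
#' @param sim a `spine_sim`.
#' @param state state to evaluate (default current).
#' @return energy in N.mm.
#' @export
total_energy <- function(sim, state = sim$state) {
  sim2 <- sim
  sim2$state <- state
  sim2$ext <- NULL
  .energy_grad(sim2, matrix(0, 18, 6), want_grad = FALSE)$E
}

#' Solve for quasi-static equilibrium
#'
#' Minimizes the total potential over the free coordinates (limited-memory
#' BFGS with analytic gradients), starting from the current state. Errors
#' if the gradient norm cannot be brought below 10 x tol; a converged
#' state never has higher energy than the start.
#'
#' @param sim a `spine_sim`.
#' @param tol gradient tolerance override.
#' @return the `spine_sim` with an updated equilibrium state and fields
#'   `residual` (gradient infinity norm) and `energy`.
#' @export
solve_equilibrium <- function(sim, tol = sim$tol) {
  for (outer in 1:8) {
    prev_rod <- sim$state$rod
    sim <- .solve_once(sim, tol)
    if (!sim$rod_free || is.null(sim$state$rod)) break
    dt <- sqrt(sum((sim$state$rod$t - prev_rod$t)^2))
    dr <- sqrt(sum(rot_log(sim$state$rod$R %*% t(prev_rod$R))^2))
    if (dt < 1e-3 && dr < 1e-5) break
  }
  sim
}

.solve_once <- function(sim, tol = sim$tol) {
  map <- .dof_map(sim)
  n <- nrow(map)
  sig <- paste(n, sim$rod_free,
               paste(vapply(sim$link, `[[`, "", "mode"), collapse = ","),
               paste(vapply(sim$link, function(l) is.null(l$Qlock), TRUE),
                     collapse = ","))
  pack <- .make_pack(sim)
  eval_g <- function(q, want_grad = TRUE) {
    U <- .q_to_disp(sim, q, map)
    eg <- .energy_grad(sim, U, want_grad, pack = pack)
    if (want_grad) {
      Gs <- eg$G
      Gs[, 4:6] <- Gs[, 4:6] / ROT_SCALE
      list(E = eg$E, g = Gs[map])
    } else list(E = eg$E)
  }
  fd_hess <- function(q, g0) {
    h <- 1e-5
    H <- matrix(0, n, n)
    for (i in 1:n) {
      qp <- q; qp[i] <- qp[i] + h
      H[, i] <- (eval_g(qp)$g - g0) / h
    }
    (H + t(H)) / 2
  }
  chol_damped <- function(H, lam) {
    repeat {
      ch <- tryCatch(chol(H + diag(rep(lam, nrow(H)))), error = function(e) NULL)
      if (!is.null(ch)) return(list(ch = ch, lam = lam))
      lam <- if (lam == 0) 1e-8 * max(diag(H)) else lam * 10
    }
  }
  # damped Newton with a cached system matrix: during a quasi-static ramp
  # the stiffness changes slowly, so the factorization carried over from
  # the previous solve usually suffices; it is refreshed whenever the
  # line search fails or the contraction rate degrades
  newt <- sim$newton
  if (is.null(newt) || !identical(newt$sig, sig)) newt <- list(sig = sig)
  q <- numeric(n)
  cur <- eval_g(q)
  E0 <- cur$E; E <- E0; g <- cur$g
  res <- max(abs(g))
  iter <- 0; refreshes <- 0; fresh_at <- -1L
  while (res > tol && iter < 60) {
    iter <- iter + 1
    if (is.null(newt$H)) {
      if (refreshes >= 30) break
      newt$H <- fd_hess(q, g)
      refreshes <- refreshes + 1
      fresh_at <- iter
      cd <- chol_damped(newt$H, 0)
      newt$chol <- cd$ch; newt$lam <- cd$lam
    }
    dq <- -backsolve(newt$chol, forwardsolve(t(newt$chol), g))
    slope <- sum(g * dq)
    tstep <- 1; ok <- FALSE
    for (ls in 1:30) {
      Ec <- eval_g(q + tstep * dq, want_grad = FALSE)$E
      if (Ec <= E + 1e-4 * tstep * slope) { ok <- TRUE; break }
      tstep <- tstep / 2
    }
    if (!ok) {
      if (fresh_at < iter) { newt$H <- NULL; next }   # stale: refresh
      # fresh Hessian but no decrease: escalate Levenberg damping
      cd <- chol_damped(newt$H, max(newt$lam * 100, 1e-6 * max(diag(newt$H))))
      newt$chol <- cd$ch; newt$lam <- cd$lam
      if (newt$lam > 1e12) break
      next
    }
    q <- q + tstep * dq
    cur <- eval_g(q)
    E <- cur$E; g <- cur$g
    res_new <- max(abs(g))
    if (res_new > 0.3 * res && res_new > 5 * tol && fresh_at < iter)
      newt$H <- NULL
    res <- res_new
  }
  if (res >= 10 * tol)
    stop(sprintf("equilibrium not reached: residual %.3e (tol %.1e)", res, tol))
  if (E > E0 + 1e-6 * max(1, abs(E0)))
    stop("energy increased during equilibrium solve")
  sim$state <- .apply_disp(sim, .q_to_disp(sim, q, map))
  sim$newton <- newt
  sim$residual <- res
  sim$energy <- total_energy(sim)
  sim
}

# Rod-local coordinates of a screw head in a given state, relative to the
# linkage's current capture point.
.head_rod_offset <- function(sim, k, state = sim$state) {
  pose <- if (!is.null(state$rod)) state$rod else sim$model$rod$pose0
  ph <- .screw_head(state, sim$model$screws[[k]])$p
  as.vector(t(pose$R) %*% (ph - pose$t)) - sim$link[[k]]$c_loc
}

# Arclength of the rod point nearest to the screw head in a state.
.nearest_station <- function(sim, k, state = sim$state) {
  rod <- sim$model$rod
  pose <- if (!is.null(state$rod)) state$rod else rod$pose0
  ph <- .screw_head(state, sim$model$screws[[k]])$p
  pl <- as.vector(t(pose$R) %*% (ph - pose$t))
  d2 <- rowSums(sweep(rod$pts, 2, pl)^2)
  i <- which.min(d2)
  lo <- rod$s[max(1, i - 1)]; hi <- rod$s[min(length(rod$s), i + 1)]
  f <- function(s) { at <- .rod_at(rod, s); sum((at$p - pl)^2) }
  stats::optimize(f, c(lo, hi))$minimum
}

# Point a linkage's capture target at the rod point nearest the head (the
# set screw clamps the rod wherever it meets the screw head).
.retarget_linkage <- function(sim, k, state = sim$state) {
  s <- .nearest_station(sim, k, state)
  at <- .rod_at(sim$model$rod, s)
  sim$link[[k]]$station <- s
  sim$link[[k]]$c_loc <- at$p
  sim$link[[k]]$tan_loc <- at$tan
  sim
}

# Global force exerted by linkage k on its screw head (zero if uncaptured).
.linkage_force <- function(sim, k, state = sim$state) {
  lk <- sim$link[[k]]
  if (lk$mode == "none") return(c(0, 0, 0))
  pose <- if (!is.null(state$rod)) state$rod else sim$model$rod$pose0
  sc <- sim$model$screws[[k]]
  ph <- .screw_head(state, sc)$p
  xt <- as.vector(pose$R %*% (lk$c_loc + lk$o_ramp)) + pose$t
  dvec <- ph - xt
  Pd <- switch(lk$mode,
    point = dvec,
    slide_axial = c(dvec[1], dvec[2], 0),
    slide_tangent = dvec - sum(dvec * lk$a_frozen) * lk$a_frozen,
    derot = sum(dvec * lk$cdir) * lk$cdir)
  -sim$penalty_k * Pd
}

# Capture a screw by ramping its linkage target from the current head
# offset to zero over `substeps` equilibrium solves.
.capture_ramp <- function(sim, ks, modes, substeps, label, monitor = NULL) {
  for (k in ks) sim <- .retarget_linkage(sim, k)
  o0 <- lapply(ks, function(k) .head_rod_offset(sim, k))
  for (j in seq_along(ks)) {
    k <- ks[j]
    if (!cone_check(sim, k, sim$state))
      stop(sprintf("capture cone violated at screw %s",
                   sim$model$screws[[k]]$level))
    sim$link[[k]]$mode <- modes[j]
    if (modes[j] == "slide_tangent") {
      pose <- if (!is.null(sim$state$rod)) sim$state$rod else sim$model$rod$pose0
      sim$link[[k]]$a_frozen <-
        as.vector(pose$R %*% sim$link[[k]]$tan_loc)
    }
  }
  gaps <- numeric(0)
  for (m in seq_len(substeps)) {
    f <- 1 - m / substeps
    for (j in seq_along(ks)) sim$link[[ks[j]]]$o_ramp <- f * o0[[j]]
    sim <- solve_equilibrium(sim)
    sim <- .monitor(sim)
    gaps <- c(gaps, max(vapply(ks, function(k)
      sqrt(sum(.head_rod_offset(sim, k)^2)), 0)))
  }
  sim$last_gaps <- gaps
  sim
}

# Continuous monitoring: record per-disc stresses and per-screw pullout
# forces of every converged equilibrium (substeps included).
.monitor <- function(sim) {
  ds <- vapply(sim$model$discs, function(d) disc_stress(sim$state, d), 0)
  names(ds) <- vapply(sim$model$discs, function(d)
    paste0(d$upper_level, "-", d$lower_level), "")
  po <- NULL
  if (!is.null(sim$model$screws)) {
    po <- vapply(seq_along(sim$model$screws),
                 function(k) pullout_force(sim, k)[["pullout"]], 0)
    names(po) <- vapply(sim$model$screws, `[[`, "", "level")
  }
  sim$monitor <- c(sim$monitor, list(list(stress = ds, pullout = po)))
  sim
}

#' Default surgical plan
#'
#' The staged segmental-translation protocol: step 1 captures the end
#' screws (cranial end free to slide and rotate axially, caudal end
#' rotation-only, the set screws not yet tightened); step 2 is a recorded
#' no-op; steps 3a-3g reduce the remaining screws onto the rod moving
#' cranial to caudal (T4 ... T12), each over incremental substeps; step 9
#' fixes the rod, loosens the captured set screws axially and derotates
#' the rod about its mean tangent axis until the measured kyphosis reaches
#' the postoperative target; step 10 locks every linkage and releases the
#' rod for the final equilibrium.
#'
#' @param reduce_substeps gap increments per reduce step (default 10).
#' @param derotate_increment rod rotation increment, degrees (default 1).
#' @param kyphosis_target,kyphosis_tol stopping rule of the derotation,
#'   degrees.
#' @return list of `surgical_step` descriptors.
#' @export
default_surgical_plan <- function(reduce_substeps = 10,
                                  derotate_increment = 1,
                                  kyphosis_target = 26, kyphosis_tol = 1) {
  reduce_levels <- c("T4", "T5", "T6", "T9", "T10", "T11", "T12")
  steps <- list(list(index = 1, label = "1", kind = "capture_ends"),
                list(index = 2, label = "2", kind = "noop"))
  for (i in seq_along(reduce_levels))
    steps[[length(steps) + 1]] <-
      list(index = 3, label = paste0("3", letters[i]), kind = "reduce",
           target = reduce_levels[i], substeps = reduce_substeps)
  steps[[length(steps) + 1]] <-
    list(index = 9, label = "9", kind = "derotate",
         increment = derotate_increment,
         kyphosis_target = kyphosis_target, kyphosis_tol = kyphosis_tol)
  steps[[length(steps) + 1]] <- list(index = 10, label = "10", kind = "lock_all")
  steps
}

#' Execute one surgical step
#'
#' Applies the step's DOF changes, solves the intermediate equilibria and
#' returns the updated context plus the measures of the converged state.
#'
#' @param sim a `spine_sim`.
#' @param step one element of a surgical plan (see
#'   [default_surgical_plan()]).
#' @return list with `sim` and `measures`.
#' @export
run_step <- function(sim, step) {
  model <- sim$model
  levels_of <- vapply(model$screws, `[[`, "", "level")
  switch(step$kind,
    capture_ends = {
      kc <- match(c("T3", "L1"), levels_of)
      sim <- .capture_ramp(sim, kc, c("slide_axial", "point"),
                           substeps = 5, label = step$label)
    },
    noop = {
      sim <- solve_equilibrium(sim)
      sim <- .monitor(sim)
    },
    reduce = {
      k <- match(step$target, levels_of)
      if (is.na(k)) stop("no screw at level ", step$target)
      sim <- .capture_ramp(sim, k, "point", substeps = step$substeps,
                           label = step$label)
    },
    derotate = {
      # fix the rod, loosen captured set screws axially (caudal screw
      # keeps rotation only), then rotate the rod about its mean tangent
      # axis until the kyphosis target is met
      # loosened set screws permit translation and rotation about the
      # global axial axis (third joint); the caudal screw keeps its full
      # capture (rod rotation only)
      kL1 <- match("L1", levels_of)
      for (k in seq_along(sim$link)) {
        if (sim$link[[k]]$mode != "none" && k != kL1)
          sim$link[[k]]$mode <- "slide_axial"
      }
      sim$rod_free <- FALSE
      # equilibrium of the released (set screws loosened) construct is the
      # baseline from which the rod is rotated
      sim <- solve_equilibrium(sim)
      sim <- .monitor(sim)
      pose <- sim$state$rod
      # derotation axis: the rod chord through the cranial and caudal
      # anchor points (the surgeon's grip axis); the end screws therefore
      # do not translate during the maneuver
      ks <- which(vapply(sim$link, function(l) l$mode != "none", TRUE))
      pend <- lapply(range(ks), function(k)
        as.vector(pose$R %*% sim$link[[k]]$c_loc) + pose$t)
      axis <- pend[[2]] - pend[[1]]
      axis <- axis / sqrt(sum(axis^2))
      centre <- pend[[1]]
      dang <- deg2rad(step$increment)
      kl <- model$measure_levels$kyphosis
      kyph <- function(s) as.numeric(cobb_angle(s, kl[1], kl[2], "sagittal"))
      err <- function(s) abs(kyph(s) - step$kyphosis_target)
      # pick the rotation sense that improves the kyphosis error
      probe <- function(sgn) {
        s2 <- sim
        s2$state$rod <- .rotate_pose(pose, sgn * 15 * dang, axis, centre)
        s2 <- solve_equilibrium(s2)
        err(s2$state)
      }
      sgn <- if (probe(+1) <= probe(-1)) +1 else -1
      best <- list(err = err(sim$state), sim = sim)
      total <- 0
      repeat {
        total <- total + step$increment
        sim$state$rod <- .rotate_pose(sim$state$rod, sgn * dang, axis, centre)
        sim <- solve_equilibrium(sim)
        sim <- .monitor(sim)
        e <- err(sim$state)
        if (e < best$err) best <- list(err = e, sim = sim)
        if (e <= step$kyphosis_tol) break
        if (total >= 200 || (e > best$err + 5)) { sim <- best$sim; break }
      }
      sim
    },
    lock_all = {
      # tighten every set screw where it stands: each captured linkage is
      # rebased to the current head-rod relative position before locking
      # (translations and rotations), so locking itself introduces no
      # force; the rod stays fixed, as it has been since the derotation
      pose <- sim$state$rod
      for (k in seq_along(sim$link)) {
        if (sim$link[[k]]$mode == "none") next
        sim$link[[k]]$o_ramp <- .head_rod_offset(sim, k)
        sim$link[[k]]$mode <- "point"
        iv <- model$screws[[k]]$body
        sim$link[[k]]$Qlock <- crossprod(pose$R, sim$state$R[[iv]])
      }
      sim <- solve_equilibrium(sim)
    },
    stop("unknown step kind: ", step$kind)
  )
  list(sim = sim, measures = per_step_measures(sim))
}

# Rotate a rigid pose about an axis through a centre point.
.rotate_pose <- function(pose, angle, axis, centre) {
  Rd <- rot_exp(angle * axis)
  list(R = Rd %*% pose$R,
       t = as.vector(Rd %*% (pose$t - centre)) + centre)
}

#' Run the full staged surgical simulation
#'
#' @param model an instrumented `spine_model` (see [instrument_spine()]).
#' @param plan list of surgical steps, default [default_surgical_plan()].
#' @param penalty_k,tol solver settings, see [spine_sim()].
#' @return object of class `spine_trajectory`: the initial state plus one
#'   converged state and measure set per step.
#' @export
run_surgery <- function(model, plan = default_surgical_plan(),
                        penalty_k = 1e4, tol = 1e-3) {
  if (is.null(model$rod) && length(plan) > 0)
    stop("model must be instrumented before surgery")
  sim <- spine_sim(model, penalty_k = penalty_k, tol = tol)
  steps <- list(list(label = "0", kind = "initial",
                     state = sim$state, residual = 0,
                     measures = per_step_measures(sim)))
  for (st in plan) {
    out <- tryCatch(run_step(sim, st), error = function(e)
      stop(sprintf("step %s (%s) failed: %s", st$label, st$kind,
                   conditionMessage(e)), call. = FALSE))
    sim <- out$sim
    steps[[length(steps) + 1]] <- list(label = st$label, kind = st$kind,
                                       state = sim$state,
                                       residual = sim$residual,
                                       measures = out$measures)
  }
  structure(list(model = model, plan = plan, sim = sim,
                 steps = steps[-1], initial = steps[[1]],
                 monitor = sim$monitor),
            class = "spine_trajectory")
}

#' @export
print.spine_trajectory <- function(x, ...) {
  cat(sprintf("Surgical trajectory: %d converged steps\n", length(x$steps)))
  for (s in x$steps) {
    a <- s$measures$angles
    po <- if (is.null(s$measures$pullout)) 0 else max(s$measures$pullout[, "pullout"])
    cat(sprintf("  step %-3s %-12s Cobb %5.1f  kyph %5.1f  lord %5.1f  max pullout %6.0f N\n",
                s$label, s$kind, a["main_cobb"], a["kyphosis_T1_T12"],
                a["lordosis_L1_L5"], po))
  }
  invisible(x)
}

#' @export
summary.spine_trajectory <- function(object, ...) {
  print(object)
  cat("\nRegion-averaged disc stresses (MPa):\n")
  print(round(region_stress_averages(object), 3))
  invisible(object)
}

#' Cobb angle and pullout trajectories plot
#'
#' @param x a `spine_trajectory`.
#' @param ... unused.
#' @export
plot.spine_trajectory <- function(x, ...) {
  labs <- vapply(x$steps, `[[`, "", "label")
  cobb <- vapply(x$steps, function(s) s$measures$angles[["main_cobb"]], 0)
  po <- vapply(x$steps, function(s)
    if (is.null(s$measures$pullout)) 0 else max(s$measures$pullout[, "pullout"]), 0)
  op <- graphics::par(mfrow = c(2, 1), mar = c(3.5, 4, 1.5, 1))
  on.exit(graphics::par(op))
  graphics::plot(seq_along(cobb), cobb, type = "b", xaxt = "n",
                 xlab = "", ylab = "main Cobb (deg)", main = "Correction")
  graphics::axis(1, at = seq_along(labs), labels = labs)
  graphics::plot(seq_along(po), po, type = "b", xaxt = "n",
                 xlab = "surgical step", ylab = "max pullout (N)")
  graphics::axis(1, at = seq_along(labs), labels = labs)
  invisible(x)
}

#' Calibrate the annulus modulus against the lateral-bending flexibility
#'
#' Simulates the flexibility (side-bending) test: a coronal-plane moment
#' applied at T1 in the direction reducing the main curve, ramped to its
#' full magnitude, on the uninstrumented model. The annulus modulus is
#' bisected until the bent main Cobb matches the profile's bending target
#' within `tol_deg`.
#'
#' @param model a `spine_model` (instrumentation, if present, is ignored).
#' @param profile profile carrying `bending_cobb` (defaults to the
#'   model's own).
#' @param moment applied moment magnitude, N.mm (default 6000 = 6 N.m,
#'   the usual magnitude of in vitro spinal flexibility protocols).
#' @param bounds annulus modulus search interval, MPa.
#' @param tol_deg bending-Cobb matching tolerance, degrees.
#' @return list: `E_annulus` (calibrated modulus, MPa), `scale` (ratio to
#'   the uncalibrated modulus), `achieved_cobb` (deg), `model` (rebuilt
#'   with the calibrated discs).
#' @export
calibrate_flexibility <- function(model, profile = model$profile,
                                  moment = 6000, bounds = c(0.5, 20),
                                  tol_deg = 1) {
  if (is.null(profile$bending_cobb)) stop("profile lacks a bending target")
  target <- profile$bending_cobb
  if (target >= profile$main_thoracic_cobb - 1e-9)
    stop("degenerate bending target: no correction demanded")
  bare <- model
  bare$rod <- NULL; bare$screws <- NULL; bare$linkages <- NULL
  sgn <- .bending_sense(bare)
  bent_cobb <- function(E) {
    m <- bare
    m$discs <- create_discs(m, E_annulus = E)
    lateral_bending_test(m, moment, sense = sgn)
  }
  # stiffer annulus -> less correction -> larger bent Cobb; a bending sim
  # that fails to converge can only happen at the soft extreme, where the
  # spine bends far beyond any physiologic target
  f <- function(E) {
    v <- tryCatch(bent_cobb(E), error = function(e) NA_real_)
    if (is.na(v)) -Inf else v - target
  }
  flo <- f(bounds[1]); fhi <- f(bounds[2])
  if (flo > 0 || fhi < 0)
    stop(sprintf("bending target %.1f deg unreachable within modulus bounds [%g, %g] MPa",
                 target, bounds[1], bounds[2]))
  lo <- bounds[1]; hi <- bounds[2]
  Emid <- (lo + hi) / 2; fm <- f(Emid)
  while ((abs(fm) > tol_deg || (hi - lo) > 0.02 * Emid) && (hi - lo) > 1e-3) {
    if (fm > 0) hi <- Emid else lo <- Emid
    Emid <- (lo + hi) / 2
    fm <- f(Emid)
  }
  out_model <- model
  out_model$discs <- create_discs(model, E_annulus = Emid)
  out_model$materials$E_annulus_calibrated <- Emid
  list(E_annulus = Emid, scale = Emid / model$materials$E_annulus,
       achieved_cobb = target + fm, model = out_model)
}

#' Simulated lateral-bending flexibility test
#'
#' Applies a pure coronal-plane moment at T1 in the direction reducing the
#' main curve, ramped adaptively to its full magnitude, and returns the
#' bent main thoracic Cobb angle. Instrumentation, if present on the
#' model, is ignored (the flexibility test precedes surgery).
#'
#' @param model a `spine_model` (its current disc stiffnesses are used).
#' @param moment moment magnitude, N.mm (default 6000 = 6 N.m).
#' @param sense +1 or -1 moment direction; found by probing when NULL.
#' @return bent main thoracic Cobb angle, degrees.
#' @export
lateral_bending_test <- function(model, moment = 6000, sense = NULL) {
  m <- model
  m$rod <- NULL; m$screws <- NULL; m$linkages <- NULL
  if (is.null(sense)) sense <- .bending_sense(m)
  sim <- spine_sim(m)
  # adaptive moment ramp: soft spines need smaller load increments
  f <- 0; df <- 0.2
  while (f < 1 - 1e-9) {
    fnext <- min(1, f + df)
    sim$ext <- list(body = 1L, comp = 5L, M = sense * fnext * moment)
    s2 <- tryCatch(solve_equilibrium(sim), error = function(e) NULL)
    if (is.null(s2)) {
      df <- df / 2
      if (df < 0.01)
        stop("lateral bending load case failed to converge")
    } else {
      sim <- s2; f <- fnext; df <- min(0.2, df * 1.5)
    }
  }
  ml <- m$measure_levels$main
  as.numeric(cobb_angle(sim$state, ml[1], ml[2], "coronal"))
}

# Sign of a T1 coronal moment (about +Y, in rotation-vector coordinates)
# that reduces the main thoracic curve, found by probing both directions
# with a small moment.
.bending_sense <- function(model, probe_moment = 1000) {
  ml <- model$measure_levels$main
  bent <- vapply(c(1, -1), function(sgn) {
    sim <- spine_sim(model)
    sim$ext <- list(body = 1L, comp = 5L, M = sgn * probe_moment)
    sim <- solve_equilibrium(sim)
    as.numeric(cobb_angle(sim$state, ml[1], ml[2], "coronal"))
  }, 0)
  if (bent[1] <= bent[2]) 1 else -1
}
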