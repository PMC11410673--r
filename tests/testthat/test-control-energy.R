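test_that("control weight modes build the documented B diagonals", {
  expect_equal(build_control_weights("uniform", n = 5)$diag, rep(1, 5))
  # thickness map extremes +0.87 / -0.59 bound B in [0.41, 1.87]
  d <- c(0.87, -0.59, 0, 0.2)
  cw <- build_control_weights("thickness_delta", d)
  expect_equal(range(cw$diag), c(0.41, 1.87))
  expect_error(build_control_weights("thickness_delta", c(0, -1.2)),
               "non-positive")
  # receptor min-max scaling spans [1, 2] for any linear map
  m <- seq(0, 7, length.out = 6)
  expect_equal(range(build_control_weights("receptor", m)$diag), c(1, 2))
  expect_error(build_control_weights("receptor", rep(3, 4)), "degenerate")
  # unit-mean rescaling
  um <- build_control_weights("unit_mean_map", c(1, 2, 3))
  expect_equal(mean(um$diag), 1)
  expect_error(build_control_weights("receptor"), "requires a modulation map")
})

test_that("optimal transition satisfies exact structural invariants", {
  set.seed(42)
  w <- random_connected_graph(8, seed = 7)
  sys <- system_from_weights(w)
  x0 <- rnorm(8); xT <- rnorm(8)
  r <- optimal_transition(sys, NULL, x0, xT, n_steps = 400)
  expect_gte(r$energy, 0)
  expect_lt(r$endpoint_error, 1e-6)
  # zero transition
  r0 <- optimal_transition(sys, NULL, rep(0, 8), rep(0, 8), n_steps = 400)
  expect_equal(r0$energy, 0, tolerance = 1e-12)
  expect_equal(max(abs(r0$inputs)), 0, tolerance = 1e-12)
  # quadratic scaling in the endpoints
  for (alpha in c(2, 0.5, -3)) {
    ra <- optimal_transition(sys, NULL, alpha * x0, alpha * xT, n_steps = 400)
    expect_equal(ra$energy, alpha^2 * r$energy, tolerance = 1e-8)
  }
  # trajectory endpoints are the requested states
  expect_equal(r$trajectory[, 1], x0, tolerance = 1e-10)
  expect_equal(r$trajectory[, ncol(r$trajectory)], xT, tolerance = 1e-6)
})

test_that("scalar system matches the closed-form minimum-energy limit", {
  sys <- scalar_system(-1)
  target <- 2 / (1 - exp(-2))
  expect_equal(minimum_energy(sys, NULL, 0, 1, T = 1), target,
               tolerance = 1e-10)
  # large rho approaches the minimum-energy solution
  r <- optimal_transition(sys, NULL, 0, 1, T = 1, rho = 1e4, n_steps = 1000)
  expect_equal(r$energy, target, tolerance = 0.02)
})

test_that("minimum energy is the Gramian form and lower-bounds optimal energy", {
  set.seed(5)
  w <- random_connected_graph(6, seed = 15)
  sys <- system_from_weights(w, c = 0.5)
  x0 <- rnorm(6)
  # free drift endpoint costs nothing
  A <- sys$a_norm
  xf <- as.numeric(as.matrix(Matrix::expm(A * 1)) %*% x0)
  expect_equal(minimum_energy(sys, NULL, x0, xf, T = 1), 0,
               tolerance = 1e-8)
  # E_min <= optimal energy at rho = 1, with monotone convergence from above
  xT <- rnorm(6)
  emin <- minimum_energy(sys, NULL, x0, xT, T = 1)
  eopt <- vapply(c(1, 1e2, 1e4), function(rho)
    optimal_transition(sys, NULL, x0, xT, rho = rho, n_steps = 600)$energy,
    numeric(1))
  expect_true(all(diff(eopt) < 0))          # decreasing in rho
  expect_true(all(eopt >= emin - 1e-10))
  expect_equal(eopt[3], emin, tolerance = 0.02)
})

test_that("closed-form energy matches the discretized QP oracle", {
  for (seed in 1:3) {
    w <- random_connected_graph(8, seed = 100 + seed)
    sys <- system_from_weights(w)
    set.seed(seed)
    x0 <- rnorm(8); xT <- rnorm(8)
    bdiag <- if (seed == 3) runif(8, 0.5, 2) else rep(1, 8)
    e_cf <- optimal_transition(sys, bdiag, x0, xT, n_steps = 1000)$energy
    e_qp <- qp_control_energy(sys$a_norm, bdiag, x0, xT, N = 400)
    expect_equal(e_cf, e_qp, tolerance = 0.01)
  }
})

test_that("transition energy matrix is consistent with per-pair calls", {
  w <- random_connected_graph(6, seed = 31)
  sys <- system_from_weights(w)
  set.seed(31)
  states <- lapply(1:3, function(i) state_map(rnorm(6), paste0("s", i)))
  te <- transition_energy_matrix(sys, NULL, states, states, n_steps = 300)
  expect_true(all(te$energies >= 0))
  expect_true(all(is.finite(te$energies)))
  for (i in 1:3) for (j in 1:3) {
    e <- optimal_transition(sys, NULL, states[[i]], states[[j]],
                            n_steps = 300)$energy
    expect_identical(te$energies[i, j], e)
  }
  # 1x1 case
  te1 <- transition_energy_matrix(sys, NULL, states[1], states[2],
                                  n_steps = 300)
  expect_equal(dim(te1$energies), c(1L, 1L))
  expect_identical(te1$energies[1, 1],
                   optimal_transition(sys, NULL, states[[1]], states[[2]],
                                      n_steps = 300)$energy)
})

test_that("transition energy is generically asymmetric under drift", {
  for (seed in 1:5) {
    w <- random_connected_graph(6, seed = 200 + seed)
    sys <- system_from_weights(w, c = 0)
    set.seed(seed)
    x0 <- rnorm(6); xT <- rnorm(6)
    e_fwd <- optimal_transition(sys, NULL, x0, xT, n_steps = 300)$energy
    e_bwd <- optimal_transition(sys, NULL, xT, x0, n_steps = 300)$energy
    expect_gt(abs(e_fwd - e_bwd) / (e_fwd + e_bwd), 1e-6)
  }
})

test_that("state maps validate and optionally unit-normalize", {
  s <- state_map(c(3, 4), "x", unit_norm = TRUE)
  expect_equal(sqrt(sum(s$values^2)), 1)
  expect_error(state_map(c(1, NA)), "non-finite")
  expect_error(state_map(c(0, 0), unit_norm = TRUE), "all-zero")
  w <- random_connected_graph(4, seed = 2)
  sys <- system_from_weights(w)
  expect_error(optimal_transition(sys, NULL, rnorm(3), rnorm(4)),
               "does not match")
  expect_error(optimal_transition(sys, NULL, rnorm(4), rnorm(4), T = -1),
               "positive")
  expect_error(optimal_transition(sys, NULL, rnorm(4), rnorm(4),
                                  n_steps = 10), "at least 100")
})
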