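#' State maps and control input weights
#'
#' A state map is one activation topography: a per-region vector x used as a
#' source state x(0) or target state x(T) of a controlled transition.
#'
#' @param values per-region numeric vector, finite.
#' @param label name of the map (e.g. a cognitive term).
#' @param unit_norm rescale to unit Euclidean norm (off by default; maps are
#'   used as given).
#' @return An object of class \code{state_map}.
#' @export
state_map <- function(values, label = "state", unit_norm = FALSE) {
  values <- as.numeric(values)
  if (any(!is.finite(values))) .stopf("state map '%s' has non-finite values", label)
  if (unit_norm) {
    nrm <- sqrt(sum(values^2))
    if (nrm == 0) .stopf("cannot unit-normalize an all-zero state map")
    values <- values / nrm
  }
  structure(list(values = values, label = label, unit_norm = unit_norm),
            class = "state_map")
}

.state_values <- function(x, n = NULL) {
  v <- if (inherits(x, "state_map")) x$values else as.numeric(x)
  if (!is.null(n) && length(v) != n)
    .stopf("state length (%d) does not match system size (%d)", length(v), n)
  v
}

.state_label <- function(x, default) {
  if (inherits(x, "state_map")) x$label else default
}

#' Build diagonal control-input weights
#'
#' The control input matrix B is diagonal; its entries locate and weight the
#' control input granted to each region. Modes:
#' \describe{
#'   \item{uniform}{all entries 1 (homogeneous control).}
#'   \item{thickness_delta}{entries \code{1 + d_i} where \code{map} holds
#'     signed per-region Cohen's d of cortical-thickness change, used as-is;
#'     regions with thinning contribute less input, thickening more.}
#'   \item{receptor}{entries \code{1 + minmax01(map)} for a non-negative
#'     regional density map scaled to [0, 1].}
#'   \item{unit_mean_map}{entries \code{map * n / sum(map)}, i.e. the map
#'     rescaled to unit mean.}
#' }
#'
#' @param mode one of \code{"uniform"}, \code{"thickness_delta"},
#'   \code{"receptor"}, \code{"unit_mean_map"}.
#' @param map per-region vector (required for non-uniform modes).
#' @param n number of regions (required for \code{mode = "uniform"} when
#'   \code{map} is absent).
#' @return An object of class \code{control_weights} with fields \code{diag},
#'   \code{mode}, \code{source_map}, \code{kappa}.
#' @export
build_control_weights <- function(mode = c("uniform", "thickness_delta",
                                           "receptor", "unit_mean_map"),
                                  map = NULL, n = NULL) {
  mode <- match.arg(mode)
  if (mode != "uniform" && is.null(map))
    .stopf("mode '%s' requires a modulation map", mode)
  d <- switch(mode,
    uniform = {
      n <- n %||% length(map)
      if (is.null(n) || n < 1) .stopf("mode 'uniform' requires n (or a map)")
      rep(1, n)
    },
    thickness_delta = {
      if (any(map <= -1))
        .stopf("thickness_delta map has entries <= -1; control weights 1 + d would be non-positive")
      1 + map
    },
    receptor = {
      rng <- range(map)
      if (diff(rng) == 0)
        .stopf("degenerate scaling: receptor map is constant, min-max rescaling undefined")
      1 + (map - rng[1]) / diff(rng)
    },
    unit_mean_map = {
      if (any(map <= 0)) .stopf("unit_mean_map requires a strictly positive map")
      map * length(map) / sum(map)
    })
  structure(list(diag = as.numeric(d), mode = mode, source_map = map,
                 kappa = "all"),
            class = "control_weights")
}

# Resolve a control_weights object (or NULL -> uniform) to a diagonal vector.
.weights_diag <- function(weights, n) {
  if (is.null(weights)) return(rep(1, n))
  d <- if (inherits(weights, "control_weights")) weights$diag else as.numeric(weights)
  if (length(d) != n)
    .stopf("control weights length (%d) does not match system size (%d)",
           length(d), n)
  if (any(d <= 0)) .stopf("control weights must be strictly positive")
  d
}

# Propagator for the 2n-dimensional state-costate system of the optimal
# control problem. From the first-order optimality conditions of
#   J = int_0^T (xT - x)'(xT - x) + rho u'u dt,  xdot = A x + B u,
# the optimal input is u* = -B' lambda / (2 rho) and the joint dynamics are
#   zdot = M z + b,  M = [A, -BB'/(2 rho); -2I, -A'],  b = [0; 2 xT].
# We precompute, for step sizes T and dt = T/n_steps,
#   Phi(s) = expm(M s)  and  Psi(s) = int_0^s expm(M r) dr
# via one block matrix exponential expm([M, I; 0, 0] * s), so that
#   z(t + s) = Phi(s) z(t) + Psi(s) b.
# Everything here depends only on (A, B, rho, T, n_steps), so a single
# propagator serves all source/target pairs of an energy matrix.
.make_propagator <- function(a_norm, bdiag, rho, T, n_steps) {
  n <- nrow(a_norm)
  m2 <- 2L * n
  BBt <- diag(bdiag^2, n)
  M <- rbind(cbind(a_norm, -BBt / (2 * rho)),
             cbind(-2 * diag(n), -t(a_norm)))
  aug <- matrix(0, 2L * m2, 2L * m2)
  aug[1:m2, 1:m2] <- M
  aug[1:m2, (m2 + 1):(2L * m2)] <- diag(m2)
  eT <- .expm(aug * T)
  ed <- .expm(aug * (T / n_steps))
  list(n = n, m2 = m2, rho = rho, T = T, n_steps = n_steps, bdiag = bdiag,
       PhiT = eT[1:m2, 1:m2], PsiT = eT[1:m2, (m2 + 1):(2L * m2)],
       Phid = ed[1:m2, 1:m2], Psid = ed[1:m2, (m2 + 1):(2L * m2)])
}

# Solve one transition with a prebuilt propagator.
.solve_transition <- function(pr, x0, xT, full = TRUE,
                              endpoint_tol = 1e-6) {
  n <- pr$n
  b <- c(rep(0, n), 2 * xT)
  dT <- as.numeric(pr$PsiT %*% b)
  E11 <- pr$PhiT[1:n, 1:n, drop = FALSE]
  E12 <- pr$PhiT[1:n, (n + 1):(2 * n), drop = FALSE]
  rc <- rcond(E12)
  if (!is.finite(rc) || rc < 1e-14)
    .stopf("ill-conditioned endpoint system (rcond = %.2g); cannot solve the boundary value problem", rc)
  lam0 <- solve(E12, xT - dT[1:n] - as.numeric(E11 %*% x0))
  z <- c(x0, lam0)
  ns <- pr$n_steps
  dt <- pr$T / ns
  db <- as.numeric(pr$Psid %*% b)
  lam_idx <- (n + 1):(2 * n)
  usq <- numeric(ns + 1)
  traj <- if (full) matrix(0, n, ns + 1) else NULL
  inputs <- if (full) matrix(0, n, ns + 1) else NULL
  for (k in 0:ns) {
    u <- -(pr$bdiag * z[lam_idx]) / (2 * pr$rho)
    usq[k + 1] <- sum(u^2)
    if (full) {
      traj[, k + 1] <- z[1:n]
      inputs[, k + 1] <- u
    }
    if (k < ns) z <- as.numeric(pr$Phid %*% z) + db
  }
  x_end <- if (full) traj[, ns + 1] else z[1:n]
  endpoint_error <- sqrt(sum((x_end - xT)^2)) / max(sqrt(sum(xT^2)), 1)
  times <- seq(0, pr$T, length.out = ns + 1)
  energy <- .trapz(times, usq)
  list(energy = energy, trajectory = traj, inputs = inputs, times = times,
       endpoint_error = endpoint_error,
       endpoint_ok = endpoint_error < endpoint_tol)
}

#' Optimal control transition between two activation states
#'
#' Steers the linear system \eqn{\dot x = A_{norm} x + B u} from a source
#' state \eqn{x(0) = x_0} to a target state \eqn{x(T) = x_T}, minimizing the
#' joint cost \deqn{J = \int_0^T (x_T - x)^T (x_T - x) + \rho\, u^T u \; dt}
#' over control inputs u. The two-point boundary value problem arising from
#' the first-order optimality conditions is solved in closed form through
#' the exponential of the 2n x 2n state-costate matrix, and the optimal
#' trajectory is evaluated forward in time on \code{n_steps} points.
#'
#' The reported energy is \eqn{\int_0^T u^T u \, dt} (the \eqn{\rho} factor
#' is a cost weighting, not part of the input magnitude), computed by
#' trapezoidal quadrature.
#'
#' @param system a \code{normalized_system} from
#'   \code{\link{normalize_adjacency}}.
#' @param weights a \code{control_weights} object, a positive diagonal
#'   vector, or NULL for uniform inputs.
#' @param x0,xT source and target states (\code{state_map} or numeric).
#' @param T time horizon (> 0). Default 1.
#' @param rho trajectory-vs-input cost weighting (> 0). Default 1.
#' @param n_steps number of sampling intervals for the trajectory and the
#'   energy quadrature (>= 100). Default 1000.
#' @param endpoint_tol relative endpoint error above which the result is
#'   flagged (and a warning emitted).
#' @return An object of class \code{transition_result}: \code{energy},
#'   \code{trajectory} (n x (n_steps+1)), \code{inputs}, \code{times},
#'   \code{endpoint_error}, \code{endpoint_ok}, \code{cost}.
#' @export
optimal_transition <- function(system, weights = NULL, x0, xT, T = 1,
                               rho = 1, n_steps = 1000,
                               endpoint_tol = 1e-6) {
  stopifnot(inherits(system, "normalized_system"))
  if (T <= 0) .stopf("time horizon T must be positive")
  if (rho <= 0) .stopf("rho must be positive")
  if (n_steps < 100) .stopf("n_steps must be at least 100")
  n <- system$n
  v0 <- .state_values(x0, n)
  vT <- .state_values(xT, n)
  bdiag <- .weights_diag(weights, n)
  pr <- .make_propagator(system$a_norm, bdiag, rho, T, n_steps)
  sol <- .solve_transition(pr, v0, vT, full = TRUE, endpoint_tol = endpoint_tol)
  if (!sol$endpoint_ok)
    .warnf("endpoint error %.3g exceeds tolerance %.3g",
           sol$endpoint_error, endpoint_tol)
  # full cost J including the state-deviation term, for reference
  dev <- colSums((vT - sol$trajectory)^2)
  usq <- colSums(sol$inputs^2)
  cost <- .trapz(sol$times, dev + rho * usq)
  structure(c(sol, list(cost = cost,
                        params = list(T = T, rho = rho, n_steps = n_steps))),
            class = "transition_result")
}

#' @export
print.transition_result <- function(x, ...) {
  cat(sprintf("transition_result: energy = %.6g, endpoint error = %.2g%s\n",
              x$energy, x$endpoint_error,
              if (x$endpoint_ok) "" else " (ABOVE TOLERANCE)"))
  invisible(x)
}

#' Minimum control energy via the finite-horizon controllability Gramian
#'
#' The least input energy that drives the system exactly from x0 to xT in
#' time T with no penalty on the trajectory (the \eqn{\rho \to \infty} limit
#' of \code{\link{optimal_transition}}):
#' \deqn{E_{min} = (x_T - e^{AT} x_0)^T W^{-1} (x_T - e^{AT} x_0)}
#' with \eqn{W = \int_0^T e^{As} B B^T e^{A^T s} ds}, evaluated through a
#' Van Loan block matrix exponential.
#'
#' @inheritParams optimal_transition
#' @param cond_tol reciprocal condition number below which the Gramian is
#'   declared numerically singular.
#' @return Scalar minimum energy.
#' @export
minimum_energy <- function(system, weights = NULL, x0, xT, T = 1,
                           cond_tol = 1e-12) {
  stopifnot(inherits(system, "normalized_system"))
  if (T <= 0) .stopf("time horizon T must be positive")
  n <- system$n
  v0 <- .state_values(x0, n)
  vT <- .state_values(xT, n)
  bdiag <- .weights_diag(weights, n)
  A <- system$a_norm
  BBt <- diag(bdiag^2, n)
  M <- rbind(cbind(-A, BBt), cbind(matrix(0, n, n), t(A)))
  FF <- .expm(M * T)
  F12 <- FF[1:n, (n + 1):(2 * n), drop = FALSE]
  F22 <- FF[(n + 1):(2 * n), (n + 1):(2 * n), drop = FALSE]  # e^{A' T}
  W <- t(F22) %*% F12
  W <- (W + t(W)) / 2
  rc <- rcond(W)
  if (!is.finite(rc) || rc < cond_tol)
    .stopf("controllability Gramian is numerically singular (rcond = %.2g); the system is not controllable over [0, T] to working precision", rc)
  v <- vT - as.numeric(t(F22) %*% v0)
  as.numeric(t(v) %*% solve(W, v))
}

#' Transition energy matrix over sets of source and target states
#'
#' Computes the optimal transition energy for every (source, target) pair.
#' Rows index source states, columns index target states. All pairs share
#' one propagator, so results are identical to per-pair
#' \code{\link{optimal_transition}} calls with the same \code{n_steps}.
#'
#' @inheritParams optimal_transition
#' @param sources,targets lists of \code{state_map}s (or numeric vectors),
#'   or a matrix with one state per column.
#' @return An object of class \code{transition_energy_matrix}: list with
#'   \code{energies} (K_source x K_target), \code{params},
#'   \code{source_labels}, \code{target_labels}, \code{endpoint_errors}.
#' @export
transition_energy_matrix <- function(system, weights = NULL, sources, targets,
                                     T = 1, rho = 1, n_steps = 1000,
                                     endpoint_tol = 1e-6) {
  stopifnot(inherits(system, "normalized_system"))
  sources <- .as_state_list(sources, "S")
  targets <- .as_state_list(targets, "T")
  if (length(sources) == 0 || length(targets) == 0)
    .stopf("source and target lists must be non-empty")
  n <- system$n
  bdiag <- .weights_diag(weights, n)
  pr <- .make_propagator(system$a_norm, bdiag, rho, T, n_steps)
  ks <- length(sources); kt <- length(targets)
  energies <- matrix(NA_real_, ks, kt)
  errs <- matrix(NA_real_, ks, kt)
  for (i in seq_len(ks)) {
    v0 <- .state_values(sources[[i]], n)
    for (j in seq_len(kt)) {
      vT <- .state_values(targets[[j]], n)
      sol <- tryCatch(.solve_transition(pr, v0, vT, full = FALSE,
                                        endpoint_tol = endpoint_tol),
                      error = function(e)
                        .stopf("transition (%d, %d) failed: %s", i, j,
                               conditionMessage(e)))
      energies[i, j] <- sol$energy
      errs[i, j] <- sol$endpoint_error
    }
  }
  sl <- vapply(seq_len(ks), function(i) .state_label(sources[[i]], paste0("S", i)), "")
  tl <- vapply(seq_len(kt), function(j) .state_label(targets[[j]], paste0("T", j)), "")
  dimnames(energies) <- dimnames(errs) <- list(sl, tl)
  structure(list(energies = energies, endpoint_errors = errs,
                 params = list(T = T, rho = rho, c = system$c,
                               n_steps = n_steps,
                               mode = if (inherits(weights, "control_weights"))
                                 weights$mode else "uniform"),
                 source_labels = sl, target_labels = tl),
            class = "transition_energy_matrix")
}

.as_state_list <- function(x, prefix) {
  if (inherits(x, "state_map")) return(list(x))
  if (is.matrix(x)) {
    labs <- colnames(x) %||% paste0(prefix, seq_len(ncol(x)))
    return(lapply(seq_len(ncol(x)),
                  function(j) state_map(x[, j], labs[j])))
  }
  if (is.numeric(x)) return(list(state_map(x, paste0(prefix, 1))))
  stopifnot(is.list(x))
  x
}

#' @export
print.transition_energy_matrix <- function(x, ...) {
  cat(sprintf("transition_energy_matrix: %d sources x %d targets (T = %g, rho = %g, c = %g, mode = %s)\n",
              nrow(x$energies), ncol(x$energies), x$params$T, x$params$rho,
              x$params$c, x$params$mode))
  invisible(x)
}
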