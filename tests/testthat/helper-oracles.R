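# Independent oracles and fixture builders used across the test files.

# Random connected weighted graph (symmetric, zero diagonal).
random_connected_graph <- function(n, density = 0.4, seed = 1) {
  set.seed(seed)
  repeat {
    w <- matrix(0, n, n)
    ut <- which(upper.tri(w))
    sel <- sample(ut, max(round(density * length(ut)), n - 1))
    w[sel] <- runif(length(sel), 0.2, 2)
    w <- w + t(w)
    g <- igraph::graph_from_adjacency_matrix(w > 0, mode = "undirected")
    if (igraph::is_connected(g)) return(w)
  }
}

# Brute-force effective resistance: explicit (e_i - e_j)' Q (e_i - e_j)
# double loop over the pseudoinverse of the Laplacian.
omega_bruteforce <- function(w) {
  n <- nrow(w)
  Q <- MASS::ginv(diag(rowSums(w)) - w)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    e <- numeric(n); e[i] <- 1; e[j] <- e[j] - 1
    out[i, j] <- drop(t(e) %*% Q %*% e)
  }
  out
}

# Brute-force network variance: explicit O(n^2) double sum.
netvar_bruteforce <- function(p, omega) {
  n <- length(p)
  acc <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    acc <- acc + p[i] * p[j] * omega[i, j]
  acc / 2
}

# Independent oracle for the optimal control problem: direct solution of the
# time-discretized quadratic program over the control sequence. Dynamics are
# discretized exactly under zero-order hold (x_{k+1} = Ad x_k + Bd u_k) and
# the cost sum_{k=0}^{N-1} dt * (|xT - x_k|^2 + rho |u_k|^2) is minimized
# subject to x_N = xT by solving the sparse KKT system of the QP.
# Returns the discrete input energy sum dt * |u_k|^2.
qp_control_energy <- function(A, bdiag, x0, xT, T = 1, rho = 1, N = 400) {
  n <- nrow(A)
  dt <- T / N
  aug <- rbind(cbind(A, diag(n)), matrix(0, n, 2 * n))
  ea <- as.matrix(Matrix::expm(aug * dt))
  Ad <- ea[1:n, 1:n]
  Bd <- ea[1:n, (n + 1):(2 * n)] %*% diag(bdiag, n)
  nu <- N * n                       # controls u_0..u_{N-1}
  nx <- N * n                       # states x_1..x_N
  nv <- nu + nx
  # quadratic cost: (1/2) v' H v + c' v
  h_diag <- c(rep(2 * dt * rho, nu),
              rep(2 * dt, (N - 1) * n), rep(0, n))
  cvec <- c(rep(0, nu), rep(-2 * dt * xT, N - 1), rep(0, n))
  # equality constraints: dynamics (N blocks) + endpoint (1 block)
  ii <- list(); jj <- list(); vv <- list(); rhs <- numeric((N + 1) * n)
  row0 <- 0L
  bidx <- function(k) (k * n + 1):((k + 1) * n)    # u_k columns, k 0-based
  xidx <- function(k) (nu + (k - 1) * n + 1):(nu + k * n) # x_k columns, k>=1
  add_block <- function(rows, cols, m) {
    nzi <- which(m != 0, arr.ind = TRUE)
    ii[[length(ii) + 1]] <<- rows[nzi[, 1]]
    jj[[length(jj) + 1]] <<- cols[nzi[, 2]]
    vv[[length(vv) + 1]] <<- m[nzi]
  }
  for (k in 0:(N - 1)) {
    rows <- (row0 + 1):(row0 + n)
    add_block(rows, xidx(k + 1), diag(n))
    add_block(rows, bidx(k), -Bd)
    if (k == 0) rhs[rows] <- Ad %*% x0
    else add_block(rows, xidx(k), -Ad)
    row0 <- row0 + n
  }
  rows <- (row0 + 1):(row0 + n)
  add_block(rows, xidx(N), diag(n))
  rhs[rows] <- xT
  nc <- (N + 1) * n
  Aeq <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                              x = unlist(vv), dims = c(nc, nv))
  H <- Matrix::sparseMatrix(i = seq_len(nv), j = seq_len(nv), x = h_diag)
  KKT <- rbind(cbind(H, Matrix::t(Aeq)),
               cbind(Aeq, Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                               x = numeric(0),
                                               dims = c(nc, nc))))
  sol <- as.numeric(Matrix::solve(KKT, c(-cvec, rhs)))
  u <- matrix(sol[1:nu], n, N)
  sum(colSums(u^2)) * dt
}

# Small helper: build a normalized_system straight from a weight matrix.
system_from_weights <- function(w, c = 0) {
  normalize_adjacency(connectome(w), c = c)
}

# Scalar (1-node) system with drift a; bypasses the connectome constructor
# (which requires a zero diagonal).
scalar_system <- function(a) {
  structure(list(a_norm = matrix(a, 1, 1), c = 0, lambda_max = abs(a),
                 n = 1L, labels = "v1"),
            class = "normalized_system")
}
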