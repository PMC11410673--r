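test_that("connectome constructor enforces symmetry, zero diagonal and non-negativity", {
  w <- matrix(c(0, 1, 1, 0), 2, 2)
  cn <- connectome(w)
  expect_equal(cn$weights, matrix(c(0, 1, 1, 0), 2, 2,
                                  dimnames = list(c("V1", "V2"), c("V1", "V2"))))
  # asymmetry beyond tolerance triggers a warning and gets symmetrized
  wa <- w; wa[1, 2] <- 1.1
  expect_warning(cna <- connectome(wa), "asymmetric")
  expect_identical(cna$weights[1, 2], cna$weights[2, 1])
  expect_error(connectome(matrix(c(0, -1, -1, 0), 2, 2)), "non-negative")
  expect_error(connectome(matrix(0, 2, 3)), "square")
})

test_that("normalize_adjacency matches the spectral formula", {
  # 2-node symmetric case: A/(1+0) - I
  cn <- connectome(matrix(c(0, 1, 1, 0), 2, 2))
  ns <- normalize_adjacency(cn, c = 0)
  expect_equal(unname(ns$a_norm), matrix(c(-1, 1, 1, -1), 2, 2))
  expect_equal(max(eigen(ns$a_norm, symmetric = TRUE)$values), 0,
               tolerance = 1e-12)
  # relative c = 0.01 * lambda_max forces the largest eigenvalue analytically
  ns2 <- normalize_adjacency(cn, c = 0.01, c_relative = TRUE)
  expect_equal(max(eigen(ns2$a_norm, symmetric = TRUE)$values),
               1 / 1.01 - 1, tolerance = 1e-12)
  # random symmetric A: largest eigenvalue of a_norm = lam/(lam + c) - 1
  for (seed in 1:5) {
    w <- random_connected_graph(10, seed = seed)
    lam <- max(abs(eigen(w, symmetric = TRUE, only.values = TRUE)$values))
    for (cc in c(0, 0.5, 2)) {
      ns3 <- normalize_adjacency(connectome(w), c = cc)
      expect_equal(max(eigen(ns3$a_norm, symmetric = TRUE)$values),
                   lam / (lam + cc) - 1, tolerance = 1e-10)
    }
  }
  expect_error(normalize_adjacency(connectome(matrix(0, 3, 3))),
               "degenerate")
})

test_that("effective resistance matches closed forms and the brute-force oracle", {
  # two nodes, weight 2: resistance 1/w = 0.5
  om2 <- effective_resistance_matrix(connectome(matrix(c(0, 2, 2, 0), 2, 2)))
  expect_equal(unname(om2$omega), matrix(c(0, 0.5, 0.5, 0), 2, 2),
               tolerance = 1e-12)
  # path of 3 unit edges: end-to-end resistance 2
  wp <- matrix(0, 3, 3); wp[1, 2] <- wp[2, 3] <- 1; wp <- wp + t(wp)
  omp <- effective_resistance_matrix(connectome(wp))
  expect_equal(omp$omega[1, 3], 2, tolerance = 1e-10)
  # complete graph K4 unit weights: 2/n = 0.5 for every pair
  wk <- matrix(1, 4, 4); diag(wk) <- 0
  omk <- effective_resistance_matrix(connectome(wk))$omega
  expect_equal(unname(omk[upper.tri(omk)]), rep(0.5, 6), tolerance = 1e-10)
  # brute-force oracle on random graphs up to 12 nodes
  for (n in c(5, 8, 12)) {
    w <- random_connected_graph(n, seed = n)
    om <- effective_resistance_matrix(connectome(w))$omega
    expect_equal(om, omega_bruteforce(w), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
  expect_identical(effective_resistance_matrix(connectome(wp))$convention,
                   "omega_as_squared_distance")
})

test_that("effective resistance is a metric on omega for small graphs", {
  for (seed in 1:3) {
    w <- random_connected_graph(7, density = 0.5, seed = seed)
    om <- effective_resistance_matrix(connectome(w))$omega
    n <- nrow(om)
    for (i in 1:n) for (j in 1:n) for (k in 1:n)
      expect_lte(om[i, j], om[i, k] + om[k, j] + 1e-12)
  }
})

test_that("disconnected graphs are rejected with component information", {
  w <- matrix(0, 4, 4); w[1, 2] <- w[3, 4] <- 1; w <- w + t(w)
  expect_error(effective_resistance_matrix(connectome(w)),
               "disconnected.*2 components")
})

test_that("network variance matches the brute-force double sum and closed forms", {
  # point mass -> 0
  wk <- matrix(1, 4, 4); diag(wk) <- 0
  om <- effective_resistance_matrix(connectome(wk))
  expect_equal(network_variance(om, c(1, 0, 0, 0), rescale = "none"), 0)
  # K4 uniform: 3/16
  expect_equal(network_variance(om, rep(0.25, 4), rescale = "none"),
               3 / 16, tolerance = 1e-12)
  # two nodes, unit edge, uniform: 0.25
  om2 <- effective_resistance_matrix(connectome(matrix(c(0, 1, 1, 0), 2, 2)))
  expect_equal(network_variance(om2, c(0.5, 0.5), rescale = "none"), 0.25,
               tolerance = 1e-12)
  # K_n closed form (n-1)/n^2 for uniform distributions
  for (n in c(3, 6, 9)) {
    wkn <- matrix(1, n, n); diag(wkn) <- 0
    omn <- effective_resistance_matrix(connectome(wkn))
    expect_equal(network_variance(omn, rep(1 / n, n), rescale = "none"),
                 (n - 1) / n^2, tolerance = 1e-10)
  }
  # brute-force double sum on random graphs and maps, including the
  # min-subtract-sum rescaling route
  for (seed in 1:5) {
    w <- random_connected_graph(9, seed = seed)
    omr <- effective_resistance_matrix(connectome(w))$omega
    set.seed(seed + 100)
    map <- runif(9, -1, 3)
    p <- (map - min(map)) / sum(map - min(map))
    expect_equal(network_variance(omr, map, rescale = "minsum"),
                 netvar_bruteforce(p, omr), tolerance = 1e-10)
  }
  expect_error(network_variance(om, rep(2, 4)), "degenerate")
})

test_that("node metrics follow the standard definitions", {
  # star graph: center degree n-1, leaves degree 1
  n <- 6
  w <- matrix(0, n, n); w[1, 2:n] <- 1; w <- w + t(w)
  nm <- node_metrics(connectome(w), partition = rep(1, n))
  expect_equal(unname(nm$binary_degree), c(n - 1, rep(1, n - 1)))
  expect_equal(unname(nm$strength), c(n - 1, rep(1, n - 1)))
  # all strength in own module -> participation 0
  expect_equal(unname(nm$participation), rep(0, n))
  # strength split equally across 2 modules -> participation 0.5
  w2 <- matrix(0, 3, 3); w2[1, 2] <- w2[1, 3] <- 1; w2 <- w2 + t(w2)
  nm2 <- node_metrics(connectome(w2), partition = c(1, 1, 2))
  expect_equal(unname(nm2$participation[1]), 0.5)
  # isolated node -> participation 0 (not NaN)
  w3 <- matrix(0, 3, 3); w3[1, 2] <- 1; w3 <- w3 + t(w3)
  nm3 <- node_metrics(connectome(w3), partition = c(1, 2, 1))
  expect_equal(unname(nm3$participation[3]), 0)
  expect_error(node_metrics(connectome(w3), partition = c(1, 2)), "cover")
})
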