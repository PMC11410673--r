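test_that("asymmetry measures are antisymmetric and match hand arithmetic", {
  te <- matrix(c(0, 3, 1, 0), 2, 2, byrow = TRUE)  # E(1->2)=3, E(2->1)=1
  a <- asymmetry_measures(te)
  expect_equal(a$delta, -t(a$delta))
  expect_equal(diag(a$delta), rep(0, 2))
  # state 2 is harder to reach than leave by 2
  expect_equal(unname(a$reach_minus_leave[2]), 2)
  expect_equal(unname(a$reach_minus_leave[1]), -2)
  # symmetric matrix: all zero deltas, row sds equal column sds
  set.seed(1)
  s <- matrix(runif(25), 5, 5); s <- s + t(s)
  as_ <- asymmetry_measures(s)
  expect_equal(max(abs(as_$delta)), 0)
  expect_equal(as_$source_sd, as_$target_sd)
  # conservation: reach-minus-leave sums to zero
  r <- matrix(rexp(49), 7, 7)
  expect_equal(sum(asymmetry_measures(r)$reach_minus_leave), 0,
               tolerance = 1e-12)
  expect_error(asymmetry_measures(matrix(0, 2, 3)), "square")
})

test_that("permutation t-test matches exhaustive enumeration and edge cases", {
  # identical samples: no effect
  res <- permutation_ttest(c(1, 2, 3), c(1, 2, 3), n_perm = 99, seed = 1)
  expect_equal(res$d, 0)
  expect_gt(res$p, 0.5)
  # constant equal samples
  res0 <- permutation_ttest(rep(2, 4), rep(2, 5))
  expect_equal(res0$p, 1)
  expect_equal(res0$d, 0)
  # exact enumeration on 3+3 matches an independent oracle
  a <- c(0.1, 0.9, 1.3); b <- c(2.4, 3.1, 2.2)
  res_ex <- permutation_ttest(a, b, exact = TRUE)
  pooled <- c(a, b)
  tfun <- function(x, y) {
    sp <- sqrt(((2) * var(x) + (2) * var(y)) / 4)
    (mean(x) - mean(y)) / (sp * sqrt(2 / 3))
  }
  tobs <- tfun(a, b)
  tall <- apply(combn(6, 3), 2, function(ix) tfun(pooled[ix], pooled[-ix]))
  expect_equal(res_ex$p, mean(abs(tall) >= abs(tobs) - 1e-12))
  expect_equal(res_ex$n_perm, 20)
  # random-permutation p approaches the enumeration value
  res_mc <- permutation_ttest(a, b, n_perm = 2000, seed = 7)
  expect_lt(abs(res_mc$p - res_ex$p), 0.05)
  # huge shift attains the add-one lower bound (samples large enough that
  # the identity split is essentially never redrawn)
  set.seed(12)
  base <- rnorm(20)
  res_sh <- permutation_ttest(base + 100, rnorm(20), n_perm = 200, seed = 2)
  expect_equal(res_sh$p, 1 / 201)
})

test_that("variability test flags target-dominated column structure", {
  # symmetric matrix: null result
  set.seed(3)
  s <- matrix(runif(36), 6, 6); s <- s + t(s)
  vt <- variability_test(s, n_perm = 500, seed = 4)
  expect_equal(vt$d, 0, tolerance = 1e-12)
  expect_gt(vt$p, 0.5)
  # column-structured matrix: energy determined by the target state, so the
  # s.d. across targets (per row) far exceeds the s.d. across sources
  levels <- c(1, 5, 20, 60, 150, 400)
  temat <- matrix(rep(levels, each = 6), 6, 6) +
    matrix(rnorm(36, 0, 0.1), 6, 6)
  vt2 <- variability_test(temat, n_perm = 1000, seed = 5)
  expect_gt(mean(vt2$sd_across_targets), mean(vt2$sd_across_sources))
  expect_gt(vt2$d, 0)
  expect_lte(vt2$p, 0.05)
})

test_that("relay analysis finds planted relays and respects metric structure", {
  # K = 2: no possible intermediate
  expect_equal(relay_analysis(matrix(c(0, 1, 2, 0), 2, 2))$relayed_fraction, 0)
  # planted relay: 1 -> 3 via 2 cheaper than direct
  te <- matrix(100, 3, 3); diag(te) <- 0
  te[1, 3] <- 10; te[1, 2] <- 3; te[2, 3] <- 4
  r <- relay_analysis(te)
  expect_true(r$relayed[1, 3])
  expect_identical(r$best_intermediate[1, 3], 2L)
  expect_gte(r$intermediate_counts[["S2"]], 1)
  # matrix satisfying the triangle inequality everywhere: nothing relayed
  set.seed(8)
  pts <- matrix(rnorm(10), 5, 2)
  dm <- as.matrix(dist(pts))
  rm_ <- relay_analysis(dm)
  expect_equal(rm_$relayed_fraction, 0)
  # two-leg cost never reported below feasibility
  expect_true(all(rm_$two_leg_cost >= dm - 1e-12, na.rm = TRUE))
})

test_that("domain median test matches enumeration and handles flat input", {
  # all values equal: p = 1 for every domain
  res <- domain_median_test(rep(1, 8), rep(c("a", "b"), 4), n_perm = 50,
                            seed = 1)
  expect_equal(res$p, c(1, 1))
  # exact enumeration oracle on m = 6
  v <- c(10, 9, 8, 1, 2, 3)
  lab <- c("hi", "hi", "hi", "lo", "lo", "lo")
  res_ex <- domain_median_test(v, lab, exact = TRUE)
  meds <- apply(combn(6, 3), 2, function(ix) median(v[ix]))
  p_hi <- mean(meds >= median(c(10, 9, 8)) - 1e-12)
  expect_equal(res_ex$p[res_ex$domain == "hi"], p_hi)
  # random permutations approach the add-one-corrected enumeration value
  res_mc <- domain_median_test(v, lab, n_perm = 2000, seed = 9)
  expect_lt(abs(res_mc$p[res_mc$domain == "hi"] - p_hi), 0.05)
  # domain holding the k largest values approaches the lower bound
  v2 <- c(100, 90, 1:8)
  lab2 <- c("top", "top", rep("rest", 8))
  res_top <- domain_median_test(v2, lab2, n_perm = 1000, seed = 2)
  expect_lt(res_top$p[res_top$domain == "top"], 0.05)
  # unlabeled states are excluded
  res_na <- domain_median_test(c(v, 1000), c(lab, NA), exact = TRUE)
  expect_equal(nrow(res_na), 2)
})

test_that("distance-energy relation is rank-invariant and rejects degenerate states", {
  set.seed(11)
  states <- matrix(rnorm(40), 8, 5)
  dm <- as.matrix(dist(t(states)))
  # energies as a strictly increasing function of distance: rho = 1
  te <- exp(dm); diag(te) <- 0
  rel <- distance_energy_relation(states, te)
  expect_equal(rel$rho, 1, tolerance = 1e-12)
  expect_equal(rel$n_pairs, 20)
  # duplicated state list: degenerate
  dup <- states[, c(1, 1, 1)]
  expect_error(distance_energy_relation(dup, matrix(1, 3, 3) - diag(3)),
               "degenerate")
})
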