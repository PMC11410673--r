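test_that("coordinate generator produces mirrored unit-sphere hemispheres", {
  co <- make_coordinates(40, seed = 1)
  expect_equal(sqrt(rowSums(co$sphere_coords^2)), rep(1, 40),
               tolerance = 1e-12)
  expect_equal(sum(co$hemisphere == "L"), 20)
  expect_equal(sum(co$hemisphere == "R"), 20)
  expect_true(all(co$sphere_coords[co$hemisphere == "L", 1] <= 0))
  co2 <- make_coordinates(40, seed = 1)
  expect_identical(co$coords3d, co2$coords3d)
  expect_error(make_coordinates(15, seed = 1), "even")
  expect_error(make_coordinates(6, seed = 1), "at least 8")
})

test_that("connectome generator hits the requested density with spatial structure", {
  co <- make_coordinates(68, seed = 2)
  cn <- make_connectome(co, density = 0.27, seed = 3)
  expect_lt(abs(edge_density(cn) - 0.27), 0.02)
  expect_identical(cn$weights, t(cn$weights))
  expect_equal(diag(cn$weights), setNames(rep(0, 68), cn$labels))
  expect_true(is_connected(cn))
  # weight-length anticorrelation, median over 20 seeds
  sp <- vapply(1:20, function(s) {
    cns <- make_connectome(co, density = 0.27, seed = 100 + s)
    d <- as.matrix(dist(co$coords3d))
    sel <- upper.tri(d) & cns$weights > 0
    cor(cns$weights[sel], d[sel], method = "spearman")
  }, numeric(1))
  expect_lt(median(sp), 0)
  # determinism
  expect_identical(make_connectome(co, seed = 3)$weights, cn$weights)
})

test_that("participant ensemble reduces to the base without noise", {
  co <- make_coordinates(20, seed = 4)
  base <- make_connectome(co, density = 0.3, seed = 5)
  parts <- make_participant_ensemble(base, k = 3, noise_sd = 0,
                                     drop_frac = 0, seed = 6)
  for (p in parts) expect_equal(p$weights, base$weights)
  parts_a <- make_participant_ensemble(base, k = 4, noise_sd = 0.3, seed = 7)
  parts_b <- make_participant_ensemble(base, k = 4, noise_sd = 0.3, seed = 7)
  expect_identical(lapply(parts_a, `[[`, "weights"),
                   lapply(parts_b, `[[`, "weights"))
})

test_that("state map smoothness controls spatial autocorrelation monotonically", {
  co <- make_coordinates(50, seed = 8)
  med_i <- vapply(c(5, 25, 80), function(sm) {
    ivals <- vapply(1:10, function(s) {
      st <- make_state_maps(co, 1, smoothness = sm, seed = 200 + s,
                            nonnegative = FALSE)
      morans_i(st[[1]]$values, coords = co$coords3d)
    }, numeric(1))
    median(ivals)
  }, numeric(1))
  expect_true(all(diff(med_i) > 0))
})

test_that("state maps honor requested moments and shapes", {
  co <- make_coordinates(30, seed = 9)
  st <- make_state_maps(co, 5, sd_range = c(0.5, 1.2),
                        mean_range = c(2, 4), seed = 10,
                        nonnegative = FALSE)
  expect_length(st, 5)
  for (s in st) {
    expect_length(s$values, 30)
    expect_gte(mean(s$values), 2 - 1e-9)
    expect_lte(mean(s$values), 4 + 1e-9)
    expect_gte(sd(s$values), 0.5 - 1e-9)
    expect_lte(sd(s$values), 1.2 + 1e-9)
  }
  stn <- make_state_maps(co, 3, seed = 11)   # default non-negative
  for (s in stn) expect_true(all(s$values >= 0))
  expect_error(make_state_maps(co, 2, sd_range = c(0, 1)), "positive")
})

test_that("modulation maps have the right sign structure and planted extremes", {
  co <- make_coordinates(30, seed = 12)
  rec <- make_modulation_map(co, "receptor", effect_regions = 1:3,
                             magnitude = 2, seed = 13)
  expect_true(all(rec$values >= 0))
  expect_identical(rec$effect_regions, 1:3)
  expect_true(all(rank(rec$values)[1:3] > 27))  # planted regions are extreme
  atr <- make_modulation_map(co, "atrophy", seed = 14)
  expect_true(min(atr$values) < 0 && max(atr$values) > 0)
  expect_gte(min(atr$values), -0.59 - 1e-9)
  expect_lte(max(atr$values), 0.87 + 1e-9)
  # no planted effect when magnitude is zero
  m0 <- make_modulation_map(co, "receptor", effect_regions = 1:3,
                            magnitude = 0, seed = 15)
  expect_identical(m0$effect_regions, integer(0))
  expect_error(make_modulation_map(co, "receptor", effect_regions = c(0, 40),
                                   magnitude = 1), "outside")
})

test_that("full synthetic dataset passes the structural invariants of its consumers", {
  ds <- make_synthetic_dataset(n = 24, k_states = 4, k_participants = 3,
                               seed = 16)
  expect_s3_class(ds$connectome, "connectome")
  expect_true(is_connected(ds$connectome))
  expect_length(ds$states, 4)
  expect_length(ds$hierarchy_map, 24)
  expect_length(ds$partition, 24)
  # every component shares the parcel count; the system normalizes and a
  # transition solves
  sys <- normalize_adjacency(ds$connectome)
  r <- optimal_transition(sys,
                          build_control_weights("receptor",
                                                ds$modulation_maps$receptor$values),
                          ds$states[[1]], ds$states[[2]], n_steps = 200)
  expect_gte(r$energy, 0)
  expect_lt(r$endpoint_error, 1e-6)
  # reproducibility of the whole bundle
  ds2 <- make_synthetic_dataset(n = 24, k_states = 4, k_participants = 3,
                                seed = 16)
  expect_identical(ds$connectome$weights, ds2$connectome$weights)
  expect_identical(ds$hierarchy_map, ds2$hierarchy_map)
})
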