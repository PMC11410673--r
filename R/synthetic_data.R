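# Seeded generators for every input the analysis assumes: spatially
# embedded weighted connectomes, participant ensembles, smooth activation
# maps, modulation maps (receptor-like and atrophy-like) and hemisphere-wise
# spherical parcel centroids. Each generator is a pure function of its
# arguments and seed.

#' Synthetic parcel coordinates
#'
#' Places n/2 parcels per hemisphere on the unit sphere (left hemisphere
#' x < 0, right x > 0; mirror-symmetric in distribution) and scales them to
#' brain-sized 3-D centroids in mm. Parcels are laid out on a golden-angle
#' spiral over the hemisphere with random angular jitter and a random
#' rotation about the inter-hemispheric axis, giving the quasi-uniform
#' tiling characteristic of atlas parcellations (clumped purely random
#' points would badly distort nearest-parcel reassignment in spin nulls).
#'
#' @param n even number of parcels (>= 8).
#' @param seed RNG seed.
#' @param radius mean centroid radius in mm.
#' @param jitter angular jitter (radians) applied to each lattice point.
#' @return List: \code{coords3d} (n x 3, mm), \code{hemisphere},
#'   \code{sphere_coords} (n x 3, unit norm).
#' @export
make_coordinates <- function(n, seed = NULL, radius = 70, jitter = 0.08) {
  if (n < 8 || n %% 2 != 0) .stopf("n must be even and at least 8 (got %d)", n)
  .seed_rng(seed)
  half <- n / 2
  golden <- pi * (3 - sqrt(5))
  one_hemi <- function(sign_x) {
    k <- seq_len(half)
    x <- (k - 0.5) / half            # depth fraction toward the pole
    phi <- golden * k + stats::runif(1, 0, 2 * pi)
    s <- sqrt(1 - x^2)
    p <- cbind(sign_x * x, s * cos(phi), s * sin(phi))
    p <- p + jitter * matrix(stats::rnorm(3 * half), half, 3)
    p[, 1] <- sign_x * abs(p[, 1])   # stay on the correct hemisphere
    p / sqrt(rowSums(p^2))
  }
  sphere <- rbind(one_hemi(-1), one_hemi(+1))
  hemisphere <- rep(c("L", "R"), each = half)
  r <- radius * (1 + stats::runif(n, -0.05, 0.05))
  list(coords3d = sphere * r, hemisphere = hemisphere,
       sphere_coords = sphere)
}

#' Synthetic spatially embedded connectome
#'
#' Samples a connected, symmetric, zero-diagonal weighted graph whose
#' connection probability decays exponentially with Euclidean distance
#' (\code{exp(-d / decay_length)}) and whose weights are positively skewed
#' (log-normal) and anticorrelated with edge length. The number of edges is
#' fixed to \code{round(density * n(n-1)/2)} by weighted sampling without
#' replacement, so the realized density matches the request.
#'
#' @param coords list from \code{\link{make_coordinates}} (or an n x 3
#'   matrix of centroids, in which case all parcels are tagged "L").
#' @param density target edge density in (0, 1].
#' @param decay_length distance scale of the connection kernel, mm.
#' @param seed RNG seed.
#' @param weight_noise_sd s.d. of the log-normal weight noise.
#' @param labels optional region labels.
#' @return A connected \code{connectome}.
#' @export
make_connectome <- function(coords, density = 0.27, decay_length = 60,
                            seed = NULL, weight_noise_sd = 0.5,
                            labels = NULL) {
  if (is.matrix(coords)) coords <- list(coords3d = coords,
                                        hemisphere = rep("L", nrow(coords)),
                                        sphere_coords = NULL)
  xyz <- coords$coords3d
  n <- nrow(xyz)
  if (density <= 0 || density > 1) .stopf("density must be in (0, 1]")
  n_pairs <- n * (n - 1) / 2
  n_edges <- round(density * n_pairs)
  if (n_edges < n - 1)
    .stopf("density %.3f gives %d edges; too few to connect %d nodes",
           density, n_edges, n)
  d <- .pairwise_dist(xyz)
  ut <- which(upper.tri(d))
  dvec <- d[ut]
  .seed_rng(seed)
  for (try in 1:20) {
    sel <- sample(length(ut), n_edges, prob = exp(-dvec / decay_length))
    w <- matrix(0, n, n)
    # weights: log-normal noise modulated by a decaying function of length
    wvals <- exp(stats::rnorm(n_edges, 0, weight_noise_sd)) *
      exp(-dvec[sel] / decay_length)
    w[ut[sel]] <- wvals
    w <- w + t(w)
    out <- connectome(w, labels = labels, coords3d = xyz,
                      hemisphere = coords$hemisphere,
                      sphere_coords = coords$sphere_coords)
    if (is_connected(out)) return(out)
  }
  .stopf("failed to sample a connected graph at density %.3f in 20 attempts",
         density)
}

#' Synthetic participant ensemble around a base connectome
#'
#' Each participant is the base connectome with log-normal weight jitter,
#' a fraction of edges dropped, and an equal number of spurious
#' distance-biased edges added (so participant densities match the base on
#' average).
#'
#' @param base the ground-truth \code{connectome}.
#' @param k number of participants (>= 1).
#' @param noise_sd s.d. of log-normal weight noise; 0 with
#'   \code{drop_frac = 0} reproduces the base exactly.
#' @param drop_frac fraction of base edges dropped (and replaced by spurious
#'   ones) per participant.
#' @param seed RNG seed.
#' @return List of \code{connectome}s.
#' @export
make_participant_ensemble <- function(base, k, noise_sd = 0.3,
                                      drop_frac = 0.1, seed = NULL) {
  stopifnot(inherits(base, "connectome"), k >= 1)
  .seed_rng(seed)
  edges <- .edge_list(base$weights)
  ne <- nrow(edges)
  d <- if (!is.null(base$coords3d)) .pairwise_dist(base$coords3d) else NULL
  non_edges <- which(upper.tri(base$weights) & base$weights == 0)
  lapply(seq_len(k), function(pid) {
    w <- matrix(0, base$n, base$n)
    keep <- rep(TRUE, ne)
    n_drop <- round(drop_frac * ne)
    if (n_drop > 0 && length(non_edges) >= n_drop) {
      keep[sample.int(ne, n_drop)] <- FALSE
      prob <- if (is.null(d)) NULL else exp(-d[non_edges] / 60)
      add <- sample(non_edges, n_drop, prob = prob)
      w[add] <- stats::median(edges$w) * exp(stats::rnorm(n_drop, 0, max(noise_sd, 0.1)))
    }
    kept <- edges[keep, ]
    w[cbind(kept$i, kept$j)] <- kept$w * exp(stats::rnorm(sum(keep), 0, noise_sd))
    w <- w + t(w)
    suppressWarnings(connectome(w, labels = base$labels,
                                coords3d = base$coords3d,
                                hemisphere = base$hemisphere,
                                sphere_coords = base$sphere_coords))
  })
}

# Smooth Gaussian-process-style field on the parcellation: distance-kernel
# mixing of white noise, standardized to zero mean / unit sd.
.smooth_field <- function(coords3d, smoothness) {
  d <- .pairwise_dist(coords3d)
  K <- exp(-d / smoothness)
  f <- as.numeric(K %*% stats::rnorm(nrow(d)))
  (f - mean(f)) / stats::sd(f)
}

#' Synthetic activation state maps
#'
#' Generates smooth (spatially autocorrelated) per-region activation maps
#' with heterogeneous means and standard deviations, emulating term-based
#' meta-analytic topographies. Each map is a distance-kernel-smoothed white
#' noise field rescaled to a drawn amplitude. Term-based meta-analytic maps
#' differ from one another mostly in overall scale (popular terms carry
#' uniformly larger association values, with the map s.d. tracking its
#' mean), so the per-map s.d. is drawn log-uniformly from \code{sd_range}
#' (spanning an order of magnitude by default) and the mean is coupled to
#' it as \code{sd * U(mean_to_sd_range)}. Supplying \code{mean_range}
#' decouples the two: the mean is then drawn uniformly from it.
#'
#' @param coords list from \code{\link{make_coordinates}} (or n x 3 matrix).
#' @param k_states number of maps.
#' @param smoothness autocorrelation length, mm (larger = smoother).
#' @param sd_range range of the per-map s.d. (log-uniform draw); must
#'   exclude 0.
#' @param mean_range optional range for an independently drawn per-map
#'   mean; default NULL couples the mean to the s.d.
#' @param mean_to_sd_range range of the mean/s.d. ratio when the mean is
#'   coupled.
#' @param seed RNG seed.
#' @param nonnegative clip values at 0 (clipping may move the realized
#'   moments slightly; with generous mean/s.d. ratios it rarely binds).
#' @return List of \code{state_map}s named \code{state01}, ...
#' @export
make_state_maps <- function(coords, k_states, smoothness = 40,
                            sd_range = c(0.3, 3), mean_range = NULL,
                            mean_to_sd_range = c(1.5, 3),
                            seed = NULL, nonnegative = TRUE) {
  if (is.matrix(coords)) coords <- list(coords3d = coords)
  if (min(sd_range) <= 0) .stopf("sd_range must be strictly positive")
  .seed_rng(seed)
  lapply(seq_len(k_states), function(s) {
    f <- .smooth_field(coords$coords3d, smoothness)
    sg <- exp(stats::runif(1, log(sd_range[1]), log(sd_range[2])))
    mu <- if (is.null(mean_range)) {
      sg * stats::runif(1, mean_to_sd_range[1], mean_to_sd_range[2])
    } else stats::runif(1, mean_range[1], mean_range[2])
    v <- mu + sg * f
    if (nonnegative) v <- pmax(v, 0)
    state_map(v, sprintf("state%02d", s))
  })
}

#' Synthetic modulation map (receptor-like or atrophy-like)
#'
#' A smooth background field with an optional localized effect planted at
#' chosen regions. \code{kind = "receptor"} yields non-negative,
#' positively skewed values (PET-density-like); \code{kind = "atrophy"}
#' yields signed Cohen's-d-like values with extremes near +0.87 / -0.59 by
#' default. Planted regions receive the map's extreme (boosted) values.
#'
#' @param coords list from \code{\link{make_coordinates}} (or n x 3 matrix).
#' @param kind \code{"receptor"} or \code{"atrophy"}.
#' @param effect_regions integer indices of regions carrying a planted
#'   boost, or NULL.
#' @param magnitude size of the planted boost (receptor: added density,
#'   >= 0; atrophy: added d, with resulting values kept in (-1, 1)).
#' @param smoothness background autocorrelation length, mm.
#' @param seed RNG seed.
#' @param d_range for \code{kind = "atrophy"}: target (min, max) of the
#'   background effect sizes.
#' @return List: \code{values} (per-region), \code{kind},
#'   \code{effect_regions}, \code{magnitude}.
#' @export
make_modulation_map <- function(coords, kind = c("receptor", "atrophy"),
                                effect_regions = NULL, magnitude = 0,
                                smoothness = 40, seed = NULL,
                                d_range = c(-0.59, 0.87)) {
  kind <- match.arg(kind)
  if (is.matrix(coords)) coords <- list(coords3d = coords)
  n <- nrow(coords$coords3d)
  if (!is.null(effect_regions) &&
      (any(effect_regions < 1) || any(effect_regions > n)))
    .stopf("effect_regions outside 1..%d", n)
  if (magnitude < 0) .stopf("magnitude must be non-negative")
  .seed_rng(seed)
  f <- .smooth_field(coords$coords3d, smoothness)
  if (kind == "receptor") {
    v <- exp(0.5 * f)                       # non-negative, right-skewed
    if (magnitude > 0 && !is.null(effect_regions))
      v[effect_regions] <- max(v) + magnitude
  } else {
    v <- d_range[1] + (f - min(f)) / diff(range(f)) * diff(d_range)
    if (magnitude > 0 && !is.null(effect_regions))
      v[effect_regions] <- pmin(v[effect_regions] + magnitude, 0.99)
  }
  list(values = v, kind = kind,
       effect_regions = if (magnitude > 0) effect_regions else integer(0),
       magnitude = magnitude)
}

#' Generator configuration and full synthetic dataset
#'
#' Assembles every input of the pipeline: a spatially embedded connectome,
#' a participant ensemble around it, activation state maps, receptor- and
#' atrophy-like modulation maps, and a smooth hierarchy map.
#'
#' @param n number of parcels (even). Default 68, the resolution of a
#'   standard whole-cortex anatomical parcellation.
#' @param density connectome edge density; default 0.27.
#' @param decay_length connection-kernel distance scale, mm.
#' @param smoothness map autocorrelation length, mm.
#' @param k_states number of activation maps; default 10.
#' @param k_participants ensemble size; default 20.
#' @param noise_sd participant weight-noise s.d.
#' @param seed RNG seed; sub-generators use fixed offsets of it.
#' @return List of class \code{synthetic_dataset}: \code{connectome},
#'   \code{participants}, \code{states}, \code{modulation_maps},
#'   \code{hierarchy_map}, \code{partition} (spatially contiguous modules
#'   from k-means of the centroids), \code{config}.
#' @export
make_synthetic_dataset <- function(n = 68, density = 0.27, decay_length = 60,
                                   smoothness = 40, k_states = 10,
                                   k_participants = 20, noise_sd = 0.3,
                                   seed = 1) {
  config <- list(n = n, density = density, decay_length = decay_length,
                 smoothness = smoothness, k_states = k_states,
                 k_participants = k_participants, noise_sd = noise_sd,
                 seed = seed)
  coords <- make_coordinates(n, seed = seed)
  conn <- make_connectome(coords, density = density,
                          decay_length = decay_length, seed = seed + 1)
  participants <- make_participant_ensemble(conn, k_participants,
                                            noise_sd = noise_sd,
                                            seed = seed + 2)
  states <- make_state_maps(coords, k_states, smoothness = smoothness,
                            seed = seed + 3)
  receptor <- make_modulation_map(coords, "receptor", seed = seed + 4,
                                  smoothness = smoothness)
  atrophy <- make_modulation_map(coords, "atrophy", seed = seed + 5,
                                 smoothness = smoothness)
  hierarchy <- local({
    .seed_rng(seed + 6)
    .smooth_field(coords$coords3d, smoothness)
  })
  partition <- local({
    .seed_rng(seed + 7)
    stats::kmeans(coords$coords3d, centers = min(4, n %/% 4))$cluster
  })
  structure(list(connectome = conn, participants = participants,
                 states = states,
                 modulation_maps = list(receptor = receptor,
                                        atrophy = atrophy),
                 hierarchy_map = hierarchy, partition = partition,
                 config = config),
            class = "synthetic_dataset")
}
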