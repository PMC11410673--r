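# Spin-rotation spatial null models: random rotations of parcel centroids
# on the sphere generate permuted versions of a cortical map that preserve
# its value distribution and spatial autocorrelation.

# Uniformly random 3x3 rotation matrix (Haar measure) via QR of a Gaussian
# matrix with sign fix-up and determinant +1.
.random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Spin permutations of spherical parcel centroids
#'
#' Generates \code{n_rot} spatial permutations of the parcellation by
#' randomly rotating parcel centroids on the unit sphere. One rotation is
#' sampled per null and applied to the left hemisphere; its mirror image
#' (reflection through the sagittal plane) is applied to the right
#' hemisphere. Each original parcel is then reassigned the value of the
#' closest rotated parcel of the same hemisphere (\code{assignment =
#' "nearest"}, which may duplicate or drop values), or matched one-to-one by
#' greedy closest-pair assignment (\code{assignment = "bijective"}, which
#' preserves the value multiset exactly).
#'
#' @param sphere_coords n x 3 unit-sphere centroids.
#' @param hemisphere per-parcel "L"/"R" tags.
#' @param n_rot number of rotations.
#' @param seed RNG seed.
#' @param assignment \code{"nearest"} (default) or \code{"bijective"}.
#' @return List of class \code{spin_null_set}: \code{permutations}
#'   (\code{n_rot} x n integer matrix; entry (r, i) is the source parcel
#'   whose value parcel i receives in null r), \code{n_rot}, \code{seed},
#'   \code{assignment}.
#' @export
spin_permutations <- function(sphere_coords, hemisphere, n_rot = 10000,
                              seed = NULL,
                              assignment = c("nearest", "bijective")) {
  assignment <- match.arg(assignment)
  sphere_coords <- as.matrix(sphere_coords)
  n <- nrow(sphere_coords)
  stopifnot(length(hemisphere) == n, all(hemisphere %in% c("L", "R")))
  nrm <- sqrt(rowSums(sphere_coords^2))
  if (any(abs(nrm - 1) > 1e-6)) {
    .warnf("sphere coordinates are not unit-norm; renormalizing")
  }
  sphere_coords <- sphere_coords / nrm
  mirror <- diag(c(-1, 1, 1))
  .seed_rng(seed)
  perms <- matrix(NA_integer_, n_rot, n)
  for (r in seq_len(n_rot)) {
    R <- .random_rotation()
    for (h in c("L", "R")) {
      idx <- which(hemisphere == h)
      Rh <- if (h == "L") R else mirror %*% R %*% mirror
      rotated <- sphere_coords[idx, , drop = FALSE] %*% t(Rh)
      # distance from each original parcel to each rotated parcel
      dmat <- outer(rowSums(sphere_coords[idx, , drop = FALSE]^2),
                    rowSums(rotated^2), "+") -
        2 * sphere_coords[idx, , drop = FALSE] %*% t(rotated)
      if (assignment == "nearest") {
        perms[r, idx] <- idx[max.col(-dmat, ties.method = "first")]
      } else {
        k <- length(idx)
        take <- integer(k)
        rows_left <- seq_len(k); cols_left <- seq_len(k)
        for (s in seq_len(k)) {
          sub <- dmat[rows_left, cols_left, drop = FALSE]
          pos <- arrayInd(which.min(sub), dim(sub))
          take[rows_left[pos[1]]] <- cols_left[pos[2]]
          rows_left <- rows_left[-pos[1]]
          cols_left <- cols_left[-pos[2]]
        }
        perms[r, idx] <- idx[take]
      }
    }
  }
  structure(list(permutations = perms, n_rot = n_rot, seed = seed,
                 assignment = assignment),
            class = "spin_null_set")
}

#' Apply one spin permutation to a map
#'
#' @param spin a \code{spin_null_set}.
#' @param map per-parcel values.
#' @param r rotation index in \code{1:n_rot}.
#' @return Permuted map.
#' @export
apply_spin <- function(spin, map, r) {
  stopifnot(inherits(spin, "spin_null_set"),
            r >= 1, r <= spin$n_rot,
            length(map) == ncol(spin$permutations))
  map[spin$permutations[r, ]]
}

#' Moran's I spatial autocorrelation
#'
#' Standard Moran's I of a per-node map under a spatial weight matrix
#' (default: inverse Euclidean distance between node coordinates, zero
#' diagonal).
#'
#' @param map per-node values (non-constant).
#' @param W spatial weight matrix (zero diagonal); overrides \code{coords}.
#' @param coords n x 3 coordinates used to build the default
#'   inverse-distance weights when \code{W} is missing.
#' @return Scalar Moran's I.
#' @export
morans_i <- function(map, W = NULL, coords = NULL) {
  n <- length(map)
  if (stats::sd(map) == 0) .stopf("Moran's I undefined for a constant map")
  if (is.null(W)) {
    if (is.null(coords)) .stopf("either W or coords must be supplied")
    d <- .pairwise_dist(as.matrix(coords))
    W <- 1 / d
    diag(W) <- 0
  }
  .check_square(W, "spatial weight matrix")
  stopifnot(nrow(W) == n)
  z <- map - mean(map)
  (n / sum(W)) * as.numeric(t(z) %*% W %*% z) / sum(z^2)
}

#' Screen a modulation map against spin nulls
#'
#' Asks, for every ordered state transition, whether heterogeneous control
#' inputs derived from the empirical modulation map make the transition
#' cheaper (facilitated) or costlier (disfacilitated) than inputs derived
#' from spatially rotated versions of the same map. Per transition,
#' facilitation p = (1 + #\{null energy <= empirical\}) / (1 + n_rot) and
#' disfacilitation analogously (two one-sided tests). For each target state
#' the result reports the percentage of source states whose transition is
#' significant at \code{alpha}.
#'
#' @param system a \code{normalized_system}.
#' @param states matrix (region x state) or list of \code{state_map}s.
#' @param map per-region modulation map.
#' @param mode \code{"thickness_delta"} or \code{"receptor"} (how the map
#'   enters the B matrix; see \code{\link{build_control_weights}}).
#' @param spin_set a \code{spin_null_set} on the same parcellation.
#' @param T,rho,n_steps transition parameters.
#' @param alpha significance level.
#' @param n_rot number of rotations to use (default: all in
#'   \code{spin_set}; must be at least 20).
#' @return List of class \code{screen_result}: \code{p_facilitated},
#'   \code{p_disfacilitated} (K x K, NA diagonal), \code{pct_facilitated},
#'   \code{pct_disfacilitated} (per target state), \code{alpha},
#'   \code{energies_empirical}.
#' @export
screen_modulation_map <- function(system, states, map,
                                  mode = c("thickness_delta", "receptor"),
                                  spin_set, T = 1, rho = 1, n_steps = 400,
                                  alpha = 0.05, n_rot = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(spin_set, "spin_null_set"))
  n_rot <- n_rot %||% spin_set$n_rot
  if (n_rot < 20)
    .stopf("n_rot = %d gives too coarse a p-value resolution; need at least 20", n_rot)
  if (n_rot > spin_set$n_rot)
    .stopf("requested %d rotations but the spin set holds %d", n_rot, spin_set$n_rot)
  states <- .as_state_list(states, "S")
  k <- length(states)
  te_for_map <- function(m) {
    w <- build_control_weights(mode, map = m)
    transition_energy_matrix(system, w, states, states, T = T, rho = rho,
                             n_steps = n_steps)$energies
  }
  emp <- te_for_map(map)
  count_le <- matrix(0L, k, k)
  count_ge <- matrix(0L, k, k)
  for (r in seq_len(n_rot)) {
    null_e <- te_for_map(apply_spin(spin_set, map, r))
    count_le <- count_le + (null_e <= emp)
    count_ge <- count_ge + (null_e >= emp)
  }
  p_fac <- (1 + count_le) / (1 + n_rot)
  p_dis <- (1 + count_ge) / (1 + n_rot)
  diag(p_fac) <- diag(p_dis) <- NA_real_
  off_n <- k - 1
  pct_fac <- 100 * colSums(p_fac < alpha, na.rm = TRUE) / off_n
  pct_dis <- 100 * colSums(p_dis < alpha, na.rm = TRUE) / off_n
  labs <- colnames(emp)
  names(pct_fac) <- names(pct_dis) <- labs
  dimnames(p_fac) <- dimnames(p_dis) <- dimnames(emp)
  structure(list(p_facilitated = p_fac, p_disfacilitated = p_dis,
                 pct_facilitated = pct_fac, pct_disfacilitated = pct_dis,
                 alpha = alpha, n_rot = n_rot, mode = mode,
                 energies_empirical = emp),
            class = "screen_result")
}
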