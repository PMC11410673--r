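#' Construct a connectome object
#'
#' A connectome is a weighted, undirected, spatially embedded region graph:
#' the structural adjacency matrix together with region labels, 3-D centroid
#' coordinates (mm), hemisphere tags and (optionally) unit-sphere centroids
#' used by spatial null models.
#'
#' Input weights must be non-negative with an (effectively) zero diagonal.
#' Near-symmetric inputs are symmetrized as \code{(A + t(A))/2}; asymmetry
#' beyond \code{1e-8} triggers a warning, exact symmetry is then enforced.
#'
#' @param weights n x n non-negative matrix of connection weights.
#' @param labels character vector of region names (default \code{V1..Vn}).
#' @param coords3d n x 3 matrix of region centroids in mm, or NULL.
#' @param hemisphere character vector of "L"/"R" tags, or NULL.
#' @param sphere_coords n x 3 matrix of unit-sphere centroids, or NULL.
#' @return An object of class \code{connectome}.
#' @export
connectome <- function(weights, labels = NULL, coords3d = NULL,
                       hemisphere = NULL, sphere_coords = NULL) {
  .check_square(weights, "connectome weights")
  n <- nrow(weights)
  if (any(!is.finite(weights))) .stopf("connectome weights must be finite")
  asym <- max(abs(weights - t(weights)))
  if (asym > 1e-8)
    .warnf("weights asymmetric (max |A - t(A)| = %.3g); symmetrizing", asym)
  weights <- (weights + t(weights)) / 2
  if (any(diag(weights) != 0)) {
    if (max(abs(diag(weights))) > 1e-12)
      .warnf("non-zero diagonal entries set to 0")
    diag(weights) <- 0
  }
  if (any(weights < 0)) .stopf("connectome weights must be non-negative")
  labels <- labels %||% paste0("V", seq_len(n))
  stopifnot(length(labels) == n)
  if (!is.null(coords3d)) {
    coords3d <- as.matrix(coords3d)
    stopifnot(nrow(coords3d) == n, ncol(coords3d) == 3)
  }
  if (!is.null(hemisphere)) {
    stopifnot(length(hemisphere) == n, all(hemisphere %in% c("L", "R")))
  }
  if (!is.null(sphere_coords)) {
    sphere_coords <- as.matrix(sphere_coords)
    stopifnot(nrow(sphere_coords) == n, ncol(sphere_coords) == 3)
  }
  dimnames(weights) <- list(labels, labels)
  structure(list(n = n, weights = weights, labels = labels,
                 coords3d = coords3d, hemisphere = hemisphere,
                 sphere_coords = sphere_coords),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  ne <- sum(x$weights[upper.tri(x$weights)] != 0)
  dens <- ne / (x$n * (x$n - 1) / 2)
  cat(sprintf("connectome: %d regions, %d edges (density %.1f%%)%s\n",
              x$n, ne, 100 * dens,
              if (is.null(x$coords3d)) "" else ", spatially embedded"))
  invisible(x)
}

#' Edge density of a connectome
#' @param conn a \code{connectome}.
#' @return Fraction of possible undirected edges present.
#' @export
edge_density <- function(conn) {
  stopifnot(inherits(conn, "connectome"))
  w <- conn$weights
  sum(w[upper.tri(w)] != 0) / (conn$n * (conn$n - 1) / 2)
}

.as_igraph <- function(conn) {
  igraph::graph_from_adjacency_matrix(conn$weights, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Test whether a connectome is connected
#'
#' Connectivity is assessed on the binary graph of non-zero weights.
#'
#' @param conn a \code{connectome}.
#' @return Logical.
#' @export
is_connected <- function(conn) {
  stopifnot(inherits(conn, "connectome"))
  igraph::is_connected(.as_igraph(conn))
}

#' Normalize an adjacency matrix into a stable continuous-time system
#'
#' Builds the drift matrix \deqn{A_{norm} = A / (|\lambda(A)_{max}| + c) - I}
#' whose largest real eigenvalue is \eqn{\lambda_{max}/(\lambda_{max}+c) - 1}:
#' exactly 0 when \code{c = 0} (marginally stable; the system approaches its
#' dominant mode) and negative when \code{c > 0} (all modes decay).
#'
#' @param conn a \code{connectome} with at least one edge.
#' @param c non-negative stabilization constant. When
#'   \code{c_relative = TRUE}, \code{c} is interpreted as a fraction of the
#'   spectral radius (e.g. \code{c = 0.01} gives \eqn{c = 0.01 |\lambda_{max}|}).
#' @param c_relative interpret \code{c} as a fraction of \eqn{|\lambda_{max}|}.
#' @return An object of class \code{normalized_system} with fields
#'   \code{a_norm}, \code{c}, \code{lambda_max}, \code{n}, \code{labels}.
#' @export
normalize_adjacency <- function(conn, c = 0, c_relative = FALSE) {
  stopifnot(inherits(conn, "connectome"))
  if (c < 0) .stopf("normalization constant c must be non-negative")
  lam <- max(abs(eigen(conn$weights, symmetric = TRUE,
                       only.values = TRUE)$values))
  if (lam <= 0) .stopf("degenerate input: all-zero adjacency (lambda_max = 0)")
  c_abs <- if (c_relative) c * lam else c
  a_norm <- conn$weights / (lam + c_abs) - diag(conn$n)
  structure(list(a_norm = a_norm, c = c_abs, lambda_max = lam,
                 n = conn$n, labels = conn$labels, connectome = conn),
            class = "normalized_system")
}

#' @export
print.normalized_system <- function(x, ...) {
  cat(sprintf("normalized_system: n = %d, lambda_max = %.4g, c = %.4g\n",
              x$n, x$lambda_max, x$c))
  invisible(x)
}

#' Effective resistance between all pairs of regions
#'
#' Computes \eqn{\omega_{ij} = (e_i - e_j)^T Q (e_i - e_j)} where \eqn{Q} is
#' the Moore-Penrose pseudoinverse of the weighted graph Laplacian. The
#' effective resistance is proportional to the commute time of a random
#' walker between the two nodes and reflects paths of all lengths, not only
#' the shortest one.
#'
#' @param conn a connected \code{connectome}.
#' @return An object of class \code{pair_distance_matrix}: list with
#'   \code{omega} (n x n), and \code{convention = "omega_as_squared_distance"}
#'   recording that \eqn{\omega} is used directly as the squared distance in
#'   \code{\link{network_variance}}.
#' @export
effective_resistance_matrix <- function(conn) {
  stopifnot(inherits(conn, "connectome"))
  comp <- igraph::components(.as_igraph(conn))
  if (comp$no > 1) {
    sizes <- paste(comp$csize, collapse = ", ")
    .stopf("graph is disconnected (%d components of sizes %s); effective resistance requires a connected graph",
           comp$no, sizes)
  }
  L <- diag(rowSums(conn$weights)) - conn$weights
  Q <- MASS::ginv(L)
  dq <- diag(Q)
  omega <- outer(dq, dq, "+") - Q - t(Q)
  omega <- (omega + t(omega)) / 2
  diag(omega) <- 0
  dimnames(omega) <- dimnames(conn$weights)
  structure(list(omega = omega, convention = "omega_as_squared_distance"),
            class = "pair_distance_matrix")
}

#' Network variance of a distribution over graph nodes
#'
#' Generalization of variance to a distribution p on the nodes of a graph:
#' \deqn{var(p) = 1/2 \sum_{i,j} p(i) p(j) d^2_{ij}} with the effective
#' resistance \eqn{\omega_{ij}} used as the squared node-to-node distance.
#' High values indicate that the mass of p is concentrated on nodes that are
#' poorly connected to the rest of the network.
#'
#' @param distances a \code{pair_distance_matrix} (or plain symmetric matrix
#'   of squared distances with zero diagonal).
#' @param map per-node values.
#' @param rescale how to turn \code{map} into a distribution:
#'   \code{"minsum"} (default; subtract the minimum, then divide by the sum),
#'   \code{"sum"} (divide non-negative values by their sum) or \code{"none"}
#'   (\code{map} is already a probability vector).
#' @return Scalar network variance.
#' @export
network_variance <- function(distances, map, rescale = c("minsum", "sum", "none")) {
  rescale <- match.arg(rescale)
  omega <- if (inherits(distances, "pair_distance_matrix")) distances$omega
           else .check_square(distances, "distance matrix")
  if (length(map) != nrow(omega))
    .stopf("map length (%d) does not match distance matrix size (%d)",
           length(map), nrow(omega))
  p <- switch(rescale,
    minsum = map - min(map),
    sum = { if (any(map < 0)) .stopf("map must be non-negative for rescale = 'sum'"); map },
    none = {
      if (any(map < 0) || abs(sum(map) - 1) > 1e-8)
        .stopf("map is not a probability vector (rescale = 'none')")
      map
    })
  if (rescale != "none") {
    s <- sum(p)
    if (s <= 0) .stopf("degenerate input: constant map has no mass after rescaling")
    p <- p / s
  }
  as.numeric(t(p) %*% omega %*% p) / 2
}

#' Per-node graph metrics
#'
#' Binary degree, strength (weighted degree), and participation coefficient
#' \eqn{P_i = 1 - \sum_m (s_{im}/s_i)^2} given a module partition. Isolated
#' nodes (zero strength) are assigned participation 0.
#'
#' @param conn a \code{connectome}.
#' @param partition per-node module labels (any atomic vector).
#' @return List with \code{binary_degree}, \code{strength},
#'   \code{participation}, class \code{node_metrics}.
#' @export
node_metrics <- function(conn, partition) {
  stopifnot(inherits(conn, "connectome"))
  if (length(partition) != conn$n)
    .stopf("partition must cover all %d nodes (got %d labels)",
           conn$n, length(partition))
  w <- conn$weights
  binary_degree <- as.integer(rowSums(w > 0))
  strength <- rowSums(w)
  mods <- unique(partition)
  # strength of node i into each module
  s_im <- vapply(mods, function(m) rowSums(w[, partition == m, drop = FALSE]),
                 numeric(conn$n))
  participation <- ifelse(strength > 0,
                          1 - rowSums((s_im / pmax(strength, .Machine$double.xmin))^2),
                          0)
  structure(list(binary_degree = stats::setNames(binary_degree, conn$labels),
                 strength = stats::setNames(strength, conn$labels),
                 participation = stats::setNames(participation, conn$labels)),
            class = "node_metrics")
}
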