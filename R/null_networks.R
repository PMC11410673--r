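# Rewired-network null models. Both kinds preserve the binary degree
# sequence and the multiset of edge weights exactly; the geometry-preserving
# variant additionally preserves the edge-length distribution (approximately,
# at bin resolution) and the weight-length relationship.

# One attempt at Maslov-Sneppen rewiring on an edge list. `binmat` is an
# optional n x n matrix of length-bin labels for every node pair; when
# given, a swap is accepted only if the two new edges fall in the same bins
# as the two removed ones (in either pairing), which approximately
# preserves the edge-length distribution. Random draws are generated in
# chunks to keep the inner loop cheap.
.rewire_once <- function(n, edges, n_swaps, binmat = NULL) {
  ne <- nrow(edges)
  ei <- edges$i; ej <- edges$j
  adj <- matrix(FALSE, n, n)
  adj[cbind(ei, ej)] <- TRUE
  adj <- adj | t(adj)
  binned <- !is.null(binmat)
  if (binned) bin <- binmat[cbind(ei, ej)]
  done <- 0L
  attempts <- 0L
  max_attempts <- n_swaps * 60L
  chunk <- 10000L
  r_e1 <- r_e2 <- r_fl <- NULL
  pos <- chunk   # force refill on first use
  while (done < n_swaps && attempts < max_attempts) {
    if (pos >= chunk) {
      r_e1 <- sample.int(ne, chunk, replace = TRUE)
      r_e2 <- sample.int(ne, chunk, replace = TRUE)
      r_fl <- stats::runif(chunk) < 0.5
      pos <- 0L
    }
    pos <- pos + 1L
    attempts <- attempts + 1L
    e1 <- r_e1[pos]; e2 <- r_e2[pos]
    if (e1 == e2) next
    a <- ei[e1]; b <- ej[e1]
    if (r_fl[pos]) { c_ <- ej[e2]; d_ <- ei[e2] } else { c_ <- ei[e2]; d_ <- ej[e2] }
    # propose (a,b),(c,d) -> (a,d),(c,b)
    if (a == d_ || c_ == b || a == c_ || b == d_) next
    if (adj[a, d_] || adj[c_, b]) next
    if (binned) {
      b1 <- bin[e1]; b2 <- bin[e2]
      nb1 <- binmat[a, d_]; nb2 <- binmat[c_, b]
      if (!((nb1 == b1 && nb2 == b2) || (nb1 == b2 && nb2 == b1))) next
      bin[e1] <- nb1; bin[e2] <- nb2
    }
    adj[a, b] <- adj[b, a] <- FALSE
    adj[c_, d_] <- adj[d_, c_] <- FALSE
    adj[a, d_] <- adj[d_, a] <- TRUE
    adj[c_, b] <- adj[b, c_] <- TRUE
    ei[e1] <- min(a, d_); ej[e1] <- max(a, d_)
    ei[e2] <- min(c_, b); ej[e2] <- max(c_, b)
    done <- done + 1L
  }
  edges$i <- ei; edges$j <- ej
  list(edges = edges, n_done = done, bin = if (binned) bin else NULL)
}

.edges_to_connectome <- function(edges, template) {
  w <- matrix(0, template$n, template$n)
  w[cbind(edges$i, edges$j)] <- edges$w
  w <- w + t(w)
  connectome(w, labels = template$labels, coords3d = template$coords3d,
             hemisphere = template$hemisphere,
             sphere_coords = template$sphere_coords)
}

#' Degree-preserving (Maslov-Sneppen) rewired null network
#'
#' Randomizes topology by repeated pairwise edge swaps. Each node's binary
#' degree and the multiset of edge weights are preserved exactly (weights
#' travel with their edge slot). Draws that leave the graph disconnected are
#' resampled.
#'
#' @param conn a connected \code{connectome}.
#' @param n_swap_per_edge target number of accepted swaps per edge.
#' @param seed RNG seed.
#' @param max_resample how many full rewirings to attempt before giving up
#'   on producing a connected null.
#' @return A rewired \code{connectome}.
#' @export
rewire_degree_preserving <- function(conn, n_swap_per_edge = 10, seed = NULL,
                                     max_resample = 50) {
  stopifnot(inherits(conn, "connectome"))
  edges0 <- .edge_list(conn$weights)
  if (nrow(edges0) < 2) .stopf("not enough edges to swap")
  .seed_rng(seed)
  n_swaps <- as.integer(n_swap_per_edge * nrow(edges0))
  for (try in seq_len(max_resample)) {
    res <- .rewire_once(conn$n, edges0, n_swaps)
    if (res$n_done < n_swaps / 2)
      .stopf("swap budget exhausted: only %d of %d swaps possible",
             res$n_done, n_swaps)
    out <- suppressWarnings(.edges_to_connectome(res$edges, conn))
    if (is_connected(out)) return(out)
  }
  .stopf("failed to produce a connected rewired network in %d attempts",
         max_resample)
}

#' Geometry-preserving rewired null network
#'
#' Like \code{\link{rewire_degree_preserving}}, but edges are binned by
#' Euclidean length and a swap is accepted only when the two new edges
#' occupy the same length bins as the two removed ones, so the edge-length
#' distribution is preserved at bin resolution. After rewiring, the original
#' weights are reassigned within each bin by length rank (longest edge gets
#' the weight that sat on the longest original edge of that bin, etc.),
#' which preserves both the exact weight multiset and the empirical
#' weight-length relationship.
#'
#' @param conn a connected \code{connectome} with \code{coords3d}.
#' @param n_bins number of equal-width length bins; bins holding fewer than
#'   2 edges are merged with their lower neighbour (with a message).
#' @param n_swap_per_edge target accepted swaps per edge.
#' @param seed RNG seed.
#' @param max_resample connectivity resampling budget.
#' @return A rewired \code{connectome}.
#' @export
rewire_geometry_preserving <- function(conn, n_bins = 10,
                                       n_swap_per_edge = 10, seed = NULL,
                                       max_resample = 50) {
  stopifnot(inherits(conn, "connectome"))
  if (is.null(conn$coords3d)) .stopf("geometry-preserving rewiring requires coords3d")
  edges0 <- .edge_list(conn$weights)
  if (nrow(edges0) < 2) .stopf("not enough edges to swap")
  d <- .pairwise_dist(conn$coords3d)
  len0 <- d[cbind(edges0$i, edges0$j)]
  brk <- seq(min(len0), max(len0), length.out = n_bins + 1)
  bin0 <- cut(len0, brk, include.lowest = TRUE, labels = FALSE)
  # merge under-filled bins downward so every label has >= 2 edges
  tab <- tabulate(bin0, n_bins)
  relab <- seq_len(n_bins)
  for (b in seq_len(n_bins)) {
    if (tab[b] > 0 && tab[b] < 2) {
      tgt <- if (b > 1) b - 1L else which(tab >= 2)[1]
      message(sprintf("length bin %d holds < 2 edges; merged with bin %d", b, tgt))
      relab[relab == b] <- tgt
      tab[tgt] <- tab[tgt] + tab[b]; tab[b] <- 0L
    }
  }
  bin0 <- relab[bin0]
  binmat <- matrix(relab[pmin(pmax(findInterval(d, brk,
                                   rightmost.closed = TRUE), 1L), n_bins)],
                   conn$n, conn$n)
  .seed_rng(seed)
  n_swaps <- as.integer(n_swap_per_edge * nrow(edges0))
  for (try in seq_len(max_resample)) {
    res <- .rewire_once(conn$n, edges0, n_swaps, binmat = binmat)
    edges <- res$edges
    # weight reassignment: within each bin, match weight rank to length rank
    len <- d[cbind(edges$i, edges$j)]
    bn <- res$bin
    for (b in unique(bn)) {
      sel <- which(bn == b)
      orig <- which(bin0 == b)
      w_sorted <- edges0$w[orig][order(len0[orig])]
      edges$w[sel[order(len[sel])]] <- w_sorted
    }
    out <- suppressWarnings(.edges_to_connectome(edges, conn))
    if (is_connected(out)) return(out)
  }
  .stopf("failed to produce a connected rewired network in %d attempts",
         max_resample)
}

#' Generate an ensemble of rewired null networks
#'
#' @param conn source \code{connectome}.
#' @param kind \code{"degree_preserving"} or \code{"geometry_preserving"}.
#' @param n_members ensemble size.
#' @param seed base RNG seed; member m uses \code{seed + m}.
#' @param ... passed to the rewiring function.
#' @return List of class \code{null_ensemble}: \code{kind}, \code{members},
#'   \code{seed}, \code{n_members}.
#' @export
null_ensemble <- function(conn, kind = c("degree_preserving",
                                         "geometry_preserving"),
                          n_members = 100, seed = 1, ...) {
  kind <- match.arg(kind)
  fn <- switch(kind, degree_preserving = rewire_degree_preserving,
               geometry_preserving = rewire_geometry_preserving)
  members <- lapply(seq_len(n_members),
                    function(m) fn(conn, seed = seed + m, ...))
  structure(list(kind = kind, members = members, seed = seed,
                 n_members = n_members),
            class = "null_ensemble")
}

#' Compare transition energies on the empirical network against nulls
#'
#' Recomputes the all-to-all mean transition energy (off-diagonal ordered
#' pairs) on the empirical connectome and on every null member, each
#' normalized afresh with the same stabilization constant, and reports the
#' one-sided non-parametric p-value for the "empirical cheaper than null"
#' direction: \eqn{p = (1 + \#\{null \le empirical\}) / (1 + n_{members})}.
#'
#' @param connectome the empirical \code{connectome}.
#' @param ensemble a \code{null_ensemble}.
#' @param states matrix (region x state) or list of \code{state_map}s.
#' @param T,rho,n_steps transition parameters (see
#'   \code{\link{optimal_transition}}).
#' @param c stabilization constant for \code{\link{normalize_adjacency}}.
#' @param weights optional \code{control_weights} applied to every network.
#' @return List of class \code{null_comparison}: \code{empirical_mean},
#'   \code{null_means}, \code{p_lower}, \code{n_failed}.
#' @export
compare_empirical_vs_nulls <- function(connectome, ensemble, states,
                                       T = 1, rho = 1, c = 0,
                                       n_steps = 1000, weights = NULL) {
  stopifnot(inherits(ensemble, "null_ensemble"))
  if (ensemble$n_members == 0) .stopf("null ensemble is empty")
  mean_energy <- function(conn) {
    sys <- normalize_adjacency(conn, c = c)
    te <- transition_energy_matrix(sys, weights, states, states,
                                   T = T, rho = rho, n_steps = n_steps)
    e <- te$energies
    mean(e[!diag(nrow(e))])
  }
  emp <- mean_energy(connectome)
  null_means <- rep(NA_real_, ensemble$n_members)
  n_failed <- 0L
  for (m in seq_len(ensemble$n_members)) {
    null_means[m] <- tryCatch(mean_energy(ensemble$members[[m]]),
                              error = function(e) { NA_real_ })
  }
  n_failed <- sum(is.na(null_means))
  if (n_failed > 0)
    .warnf("%d null members failed and were excluded", n_failed)
  ok <- null_means[!is.na(null_means)]
  p_lower <- (1 + sum(ok <= emp)) / (1 + length(ok))
  structure(list(empirical_mean = emp, null_means = null_means,
                 p_lower = p_lower, n_failed = n_failed,
                 kind = ensemble$kind),
            class = "null_comparison")
}
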