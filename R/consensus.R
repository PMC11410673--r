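#' Distance-dependent group-consensus connectome
#'
#' Builds a representative group connectome from an ensemble of participant
#' matrices while preserving, on average, both the edge density and the
#' intra-/inter-hemispheric edge length distributions of the individual
#' networks. Candidate edges are binned by Euclidean centroid distance,
#' separately for intra- and inter-hemispheric pairs; within each bin the
#' procedure retains the edges most consistently present across participants,
#' up to the mean per-participant edge count of that bin. The weight of each
#' retained edge is the mean of the corresponding non-zero participant
#' weights.
#'
#' @param participants list of n x n non-negative matrices, identical shape.
#' @param coords3d n x 3 region centroids in mm.
#' @param hemisphere per-region "L"/"R" tags; when NULL all pairs are
#'   treated as a single (intra-hemispheric) class.
#' @param n_bins number of distance bins per class; default
#'   \code{ceiling(sqrt(mean participant edge count))}.
#' @param labels optional region labels for the result.
#' @param sphere_coords optional unit-sphere centroids carried through.
#' @return A \code{connectome} holding the consensus network.
#' @export
build_consensus <- function(participants, coords3d, hemisphere = NULL,
                            n_bins = NULL, labels = NULL,
                            sphere_coords = NULL) {
  if (!is.list(participants) || length(participants) == 0)
    .stopf("participants must be a non-empty list of matrices")
  dims <- vapply(participants, function(m) dim(as.matrix(m)), integer(2))
  if (any(dims != dims[1, 1]))
    .stopf("participant matrices have mismatched shapes")
  n <- dims[1, 1]
  coords3d <- as.matrix(coords3d)
  stopifnot(nrow(coords3d) == n)
  k <- length(participants)
  arr <- array(unlist(participants), dim = c(n, n, k))

  up <- upper.tri(matrix(0, n, n))
  d <- .pairwise_dist(coords3d)
  nz <- arr != 0
  count <- apply(nz, c(1, 2), sum)                 # consistency per pair
  wsum <- apply(arr, c(1, 2), sum)
  mean_w <- ifelse(count > 0, wsum / count, 0)     # mean of non-zero weights

  if (is.null(n_bins)) {
    mean_edges <- mean(vapply(participants,
                              function(m) sum(m[up] != 0), numeric(1)))
    n_bins <- max(1L, ceiling(sqrt(mean_edges)))
  }

  if (is.null(hemisphere)) {
    class_of <- matrix("intra", n, n)
  } else {
    class_of <- ifelse(outer(hemisphere, hemisphere, "=="), "intra", "inter")
  }

  keep <- matrix(FALSE, n, n)
  for (cl in unique(class_of[up])) {
    in_class <- up & class_of == cl
    cand <- which(in_class & count > 0)
    if (length(cand) == 0) next
    rng <- range(d[in_class])
    brk <- seq(rng[1], rng[2], length.out = n_bins + 1)
    bin_all <- cut(d[in_class], brk, include.lowest = TRUE, labels = FALSE)
    bin_cand <- cut(d[cand], brk, include.lowest = TRUE, labels = FALSE)
    idx_all <- which(in_class)
    for (b in seq_len(n_bins)) {
      cb <- cand[bin_cand == b]
      if (length(cb) == 0) next
      # mean per-participant edge count in this class & bin
      pairs_b <- idx_all[bin_all == b]
      target <- round(sum(count[pairs_b]) / k)
      if (target <= 0) next
      ord <- order(count[cb], mean_w[cb], decreasing = TRUE)
      keep[cb[ord[seq_len(min(target, length(cb)))]]] <- TRUE
    }
  }
  w_out <- matrix(0, n, n)
  w_out[keep] <- mean_w[keep]
  w_out <- w_out + t(w_out)
  connectome(w_out, labels = labels, coords3d = coords3d,
             hemisphere = hemisphere, sphere_coords = sphere_coords)
}
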