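# Statistics computed on a square transition-energy matrix: asymmetry,
# source/target variability, relay (intermediate-state) analysis, domain
# permutation tests, and the energy-distance relation.

.te_energies <- function(TE) {
  if (inherits(TE, "transition_energy_matrix")) TE$energies
  else .check_square(as.matrix(TE), "transition energy matrix")
}

.te_square <- function(TE) {
  e <- .te_energies(TE)
  if (nrow(e) != ncol(e))
    .stopf("a square transition energy matrix is required (got %d x %d)",
           nrow(e), ncol(e))
  e
}

#' Transition asymmetry measures
#'
#' For a square energy matrix E with E[i, j] the energy of the transition
#' i -> j, computes the pairwise asymmetry \eqn{\Delta(i,j) = E(i \to j) -
#' E(j \to i)}, the per-state reach-minus-leave score (mean of
#' \eqn{\Delta(\cdot, j)} over sources; positive = harder to reach than to
#' leave), and the per-row / per-column standard deviations of E
#' (variability across targets for each source, and across sources for each
#' target). Diagonal entries are excluded from all summaries.
#'
#' @param TE a \code{transition_energy_matrix} or square matrix
#'   (rows = sources, columns = targets).
#' @return List of class \code{asymmetry_report}: \code{delta},
#'   \code{reach_minus_leave}, \code{source_sd}, \code{target_sd}.
#' @export
asymmetry_measures <- function(TE) {
  e <- .te_square(TE)
  k <- nrow(e)
  delta <- e - t(e)
  off <- !diag(k)
  rml <- vapply(seq_len(k), function(j) mean(delta[off[, j], j]), numeric(1))
  source_sd <- vapply(seq_len(k), function(i) stats::sd(e[i, off[i, ]]), numeric(1))
  target_sd <- vapply(seq_len(k), function(j) stats::sd(e[off[, j], j]), numeric(1))
  labs <- rownames(e) %||% paste0("S", seq_len(k))
  structure(list(delta = delta,
                 reach_minus_leave = stats::setNames(rml, labs),
                 source_sd = stats::setNames(source_sd, labs),
                 target_sd = stats::setNames(target_sd, labs)),
            class = "asymmetry_report")
}

#' Permutation t-test for variability across targets vs across sources
#'
#' Tests whether the energy matrix varies more along the target (column)
#' dimension than along the source (row) dimension: the per-source standard
#' deviations across target states (\code{source_sd}, one value per row)
#' are compared against the per-target standard deviations across source
#' states (\code{target_sd}, one per column) with a two-sided
#' label-permutation t-test. A positive t (and Cohen's d) means the
#' destination of a transition matters more than its origin.
#'
#' @param TE square transition energy matrix.
#' @param n_perm number of label permutations.
#' @param seed RNG seed.
#' @return The \code{\link{permutation_ttest}} result (t, p, Cohen's d) plus
#'   \code{sd_across_targets} (per-row) and \code{sd_across_sources}
#'   (per-column) vectors.
#' @export
variability_test <- function(TE, n_perm = 10000, seed = NULL) {
  a <- asymmetry_measures(TE)
  if (length(a$target_sd) < 3)
    .stopf("variability test requires at least 3 states")
  res <- permutation_ttest(a$source_sd, a$target_sd, n_perm = n_perm,
                           seed = seed)
  c(res, list(sd_across_targets = a$source_sd,
              sd_across_sources = a$target_sd))
}

#' Relay (intermediate-state) analysis
#'
#' For every ordered pair (i, j), compares the direct transition energy
#' E(i -> j) with the cheapest two-leg route through a single intermediate
#' state k: \eqn{\min_{k \ne i,j} E(i \to k) + E(k \to j)}. A pair is
#' "relayed" when some intermediate route is strictly cheaper than the
#' direct one.
#'
#' @param TE square transition energy matrix.
#' @return List of class \code{relay_report}: \code{relayed_fraction},
#'   \code{relayed} (logical K x K, NA diagonal), \code{best_intermediate}
#'   (index of the cheapest intermediate per pair; NA on the diagonal and
#'   for K = 2), \code{intermediate_counts} (times each state is the chosen
#'   intermediate of a relayed pair), \code{two_leg_cost}.
#' @export
relay_analysis <- function(TE) {
  e <- .te_square(TE)
  k <- nrow(e)
  relayed <- matrix(NA, k, k)
  best <- matrix(NA_integer_, k, k)
  two_leg <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    mids <- setdiff(seq_len(k), c(i, j))
    if (length(mids) == 0) { relayed[i, j] <- FALSE; next }
    costs <- e[i, mids] + e[mids, j]
    m <- which.min(costs)
    two_leg[i, j] <- costs[m]
    best[i, j] <- mids[m]
    relayed[i, j] <- costs[m] < e[i, j]
  }
  n_pairs <- k * (k - 1)
  counts <- tabulate(best[which(relayed)], nbins = k)
  labs <- rownames(e) %||% paste0("S", seq_len(k))
  structure(list(relayed_fraction = sum(relayed, na.rm = TRUE) / n_pairs,
                 relayed = relayed, best_intermediate = best,
                 two_leg_cost = two_leg,
                 intermediate_counts = stats::setNames(counts, labs)),
            class = "relay_report")
}

#' Two-sided permutation t-test with Cohen's d
#'
#' Non-parametric two-sample test: the two-sample t statistic (pooled
#' variance) is recomputed under random reassignment of group labels; the
#' two-sided p-value uses the add-one correction
#' \eqn{p = (1 + \#\{|t^*| \ge |t|\}) / (1 + n_{perm})}. The effect size is
#' Cohen's d with pooled standard deviation. With \code{exact = TRUE} all
#' \eqn{\binom{n_a+n_b}{n_a}} group assignments are enumerated instead and
#' p is the exact fraction (the observed split counts itself).
#'
#' @param a,b numeric samples.
#' @param n_perm number of random permutations (ignored when exact).
#' @param seed RNG seed.
#' @param exact enumerate all label assignments (feasible for small samples).
#' @return List: \code{t}, \code{p}, \code{d}, \code{n_perm}, \code{exact}.
#' @export
permutation_ttest <- function(a, b, n_perm = 10000, seed = NULL,
                              exact = FALSE) {
  if (length(a) == 0 || length(b) == 0) .stopf("both samples must be non-empty")
  if (!exact && n_perm < 1) .stopf("n_perm must be at least 1")
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  tstat <- function(x, y) {
    sp2 <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
      (length(x) + length(y) - 2)
    if (sp2 <= 0) {
      if (mean(x) == mean(y)) return(0)
      return(sign(mean(x) - mean(y)) * Inf)
    }
    (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
  }
  t_obs <- tstat(a, b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  d <- if (sp2 <= 0) { if (mean(a) == mean(b)) 0 else sign(mean(a) - mean(b)) * Inf
       } else (mean(a) - mean(b)) / sqrt(sp2)
  if (sp2 <= 0 && mean(a) == mean(b))
    return(list(t = 0, p = 1, d = 0, n_perm = 0L, exact = TRUE))
  thr <- abs(t_obs) - 1e-12
  if (exact) {
    splits <- utils::combn(na + nb, na)
    tp <- apply(splits, 2, function(idx) tstat(pooled[idx], pooled[-idx]))
    p <- mean(abs(tp) >= thr)
    return(list(t = t_obs, p = p, d = d, n_perm = ncol(splits), exact = TRUE))
  }
  .seed_rng(seed)
  count <- 0L
  for (r in seq_len(n_perm)) {
    idx <- sample.int(na + nb, na)
    if (abs(tstat(pooled[idx], pooled[-idx])) >= thr) count <- count + 1L
  }
  list(t = t_obs, p = (1 + count) / (1 + n_perm), d = d,
       n_perm = n_perm, exact = FALSE)
}

#' One-sided permutation test on per-domain medians
#'
#' For each labeled domain, asks whether its member states carry a higher
#' median value than expected if the same number of states were drawn at
#' random from the labeled pool. p = (1 + #\{null median >= observed\}) /
#' (1 + n_perm), one-sided with add-one correction; \code{exact = TRUE}
#' enumerates all subsets instead.
#'
#' @param values per-state values (e.g. reach-minus-leave asymmetry).
#' @param labels per-state domain labels; NA = unlabeled (excluded).
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @param exact enumerate all subsets of each domain's size.
#' @return Data frame with one row per domain: \code{domain}, \code{n},
#'   \code{median}, \code{p}.
#' @export
domain_median_test <- function(values, labels, n_perm = 1000, seed = NULL,
                               exact = FALSE) {
  stopifnot(length(values) == length(labels))
  keep <- !is.na(labels)
  v <- values[keep]; lab <- labels[keep]
  doms <- unique(lab)
  if (any(table(lab) == 0)) .stopf("domain with zero members")
  .seed_rng(seed)
  m <- length(v)
  rows <- lapply(doms, function(d) {
    k <- sum(lab == d)
    obs <- stats::median(v[lab == d])
    if (exact) {
      subs <- utils::combn(m, k)
      meds <- apply(subs, 2, function(idx) stats::median(v[idx]))
      p <- mean(meds >= obs - 1e-12)
    } else {
      count <- 0L
      for (r in seq_len(n_perm)) {
        if (stats::median(v[sample.int(m, k)]) >= obs - 1e-12)
          count <- count + 1L
      }
      p <- (1 + count) / (1 + n_perm)
    }
    data.frame(domain = d, n = k, median = obs, p = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Spearman relation between state distance and transition energy
#'
#' Pools all ordered off-diagonal state pairs and rank-correlates the
#' Euclidean distance between the two state vectors with the transition
#' energy.
#'
#' @param states matrix with one state per column (region x state), or list
#'   of \code{state_map}s, in the order of the energy matrix.
#' @param TE square transition energy matrix over the same states.
#' @return List: \code{rho}, \code{p}, \code{n_pairs}.
#' @export
distance_energy_relation <- function(states, TE) {
  e <- .te_square(TE)
  k <- nrow(e)
  if (is.list(states) && !is.matrix(states))
    states <- vapply(states, .state_values, numeric(length(.state_values(states[[1]]))))
  states <- as.matrix(states)
  if (ncol(states) != k)
    .stopf("number of states (%d) does not match energy matrix size (%d)",
           ncol(states), k)
  dmat <- as.matrix(stats::dist(t(states)))
  off <- !diag(k)
  dd <- dmat[off]; ee <- e[off]
  if (length(dd) < 3) .stopf("fewer than 3 state pairs")
  if (stats::sd(dd) == 0)
    .stopf("degenerate input: all pairwise state distances are equal (duplicated states?)")
  if (any(dd == 0))
    .warnf("%d state pairs have zero distance (duplicated states)", sum(dd == 0))
  ct <- suppressWarnings(stats::cor.test(dd, ee, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n_pairs = length(dd))
}
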