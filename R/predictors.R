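# Characterizing target states and explaining transition-cost variation:
# per-state predictor table, partial rank correlations, dominance analysis.

#' Partial Spearman correlation
#'
#' Rank-based partial correlation: y, x and the covariates are converted to
#' ranks (average ranks for ties), y and x are residualized on the
#' covariates by least squares, and the Pearson correlation of the residuals
#' is returned. With no covariates this reduces exactly to the plain
#' Spearman coefficient. The p-value uses the t approximation with
#' \code{n - 2 - k} degrees of freedom (k = number of covariates).
#'
#' @param y,x numeric vectors.
#' @param covariates numeric vector, matrix (one covariate per column), or
#'   NULL.
#' @return List: \code{rho}, \code{p}, \code{n}, \code{df}.
#' @export
partial_spearman <- function(y, x, covariates = NULL) {
  stopifnot(length(y) == length(x))
  n <- length(y)
  k <- if (is.null(covariates)) 0L else NCOL(covariates)
  if (n < 4 + k) .stopf("need at least %d observations (got %d)", 4 + k, n)
  ry <- rank(y); rx <- rank(x)
  if (k == 0) {
    res_y <- ry - mean(ry); res_x <- rx - mean(rx)
  } else {
    Z <- apply(as.matrix(covariates), 2, rank)
    X <- cbind(1, Z)
    qx <- qr(X)
    if (qx$rank < ncol(X))
      .stopf("rank-deficient covariates (rank %d < %d)", qx$rank, ncol(X))
    res_y <- stats::resid(stats::lm.fit(X, ry))
    res_x <- stats::resid(stats::lm.fit(X, rx))
  }
  # residuals that vanish to numerical noise mean the variable is fully
  # explained by the covariates: the partial association is 0 by definition
  tol <- 1e-10 * n
  if (stats::sd(res_y) < tol || stats::sd(res_x) < tol)
    return(list(rho = 0, p = 1, n = n, df = n - 2L - k))
  rho <- stats::cor(res_y, res_x)
  df <- n - 2L - k
  tval <- rho * sqrt(df / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tval), df)
  list(rho = rho, p = p, n = n, df = df)
}

#' Dominance analysis of regression predictors
#'
#' Partitions the full-model R-squared of a linear regression across
#' predictors by fitting all \eqn{2^p - 1} predictor subsets. The total
#' dominance of predictor i is the average (first within subset size, then
#' across sizes) of the incremental R-squared gained by adding i to a
#' submodel; totals sum exactly to the full-model (unadjusted) R-squared.
#'
#' @param y response vector.
#' @param X predictor matrix (one predictor per column), p <= 15 columns.
#' @return List of class \code{dominance_report}: \code{dominance} (named,
#'   one entry per predictor), \code{r2_full}, \code{r2_subsets}.
#' @export
dominance_analysis <- function(y, X) {
  X <- as.matrix(X)
  p <- ncol(X); n <- nrow(X)
  if (p > 15) .stopf("exhaustive dominance analysis supports at most 15 predictors (got %d)", p)
  if (n <= p + 2) .stopf("need n > p + 2 observations (n = %d, p = %d)", n, p)
  stopifnot(length(y) == n)
  cn <- colnames(X) %||% paste0("x", seq_len(p))
  qx <- qr(cbind(1, X))
  if (qx$rank < p + 1) {
    bad <- cn[setdiff(seq_len(p), qx$pivot[seq_len(qx$rank)] - 1L)]
    .stopf("collinear predictors: %s", paste(bad, collapse = ", "))
  }
  tss <- sum((y - mean(y))^2)
  if (tss == 0) .stopf("response has zero variance")
  n_masks <- bitwShiftL(1L, p) - 1L
  r2 <- numeric(n_masks + 1L)          # r2[mask + 1]; empty model = 0
  for (mask in seq_len(n_masks)) {
    cols <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(p) - 1L)) != 0L)
    fit <- stats::lm.fit(cbind(1, X[, cols, drop = FALSE]), y)
    r2[mask + 1L] <- 1 - sum(fit$residuals^2) / tss
  }
  dominance <- numeric(p)
  for (i in seq_len(p)) {
    bit <- bitwShiftL(1L, i - 1L)
    others <- setdiff(seq_len(p), i)
    # incremental contributions grouped by submodel size 0..p-1
    by_size <- vector("list", p)
    masks_wo <- Filter(function(m) bitwAnd(m, bit) == 0L, 0:n_masks)
    for (m in masks_wo) {
      sz <- sum(bitwAnd(m, bitwShiftL(1L, seq_len(p) - 1L)) != 0L)
      by_size[[sz + 1L]] <- c(by_size[[sz + 1L]], r2[m + bit + 1L] - r2[m + 1L])
    }
    dominance[i] <- mean(vapply(by_size, mean, numeric(1)))
  }
  structure(list(dominance = stats::setNames(dominance, cn),
                 r2_full = r2[n_masks + 1L],
                 r2_subsets = r2[-1]),
            class = "dominance_report")
}

#' Per-state predictor table
#'
#' Characterizes each activation state by its map mean and standard
#' deviation, its Spearman correlation with regional graph metrics (binary
#' degree, strength, participation coefficient) and with a supplied cortical
#' hierarchy map, its network variance on the connectome, and the mean
#' energy required to reach it (column mean of the transition energy matrix,
#' diagonal excluded).
#'
#' @param states matrix (region x state) or list of \code{state_map}s.
#' @param conn the \code{connectome}.
#' @param hierarchy_map per-region vector (e.g. the principal functional
#'   gradient), injected as an input.
#' @param TE square \code{transition_energy_matrix} over the same states
#'   (rows sources, columns targets), or NULL to skip the energy column.
#' @param partition per-region module labels for the participation
#'   coefficient.
#' @return Data frame, one row per state.
#' @export
state_predictor_table <- function(states, conn, hierarchy_map, TE = NULL,
                                  partition = NULL) {
  stopifnot(inherits(conn, "connectome"))
  states <- .as_state_list(states, "S")
  k <- length(states)
  smat <- vapply(states, function(s) .state_values(s, conn$n),
                 numeric(conn$n))
  labs <- vapply(seq_len(k), function(i) .state_label(states[[i]], paste0("S", i)), "")
  partition <- partition %||% rep(1L, conn$n)
  nm <- node_metrics(conn, partition)
  stopifnot(length(hierarchy_map) == conn$n)
  omega <- effective_resistance_matrix(conn)
  sp_cor <- function(s, v) {
    if (stats::sd(v) == 0 || stats::sd(s) == 0) return(NA_real_)
    stats::cor(s, v, method = "spearman")
  }
  energy_to_reach <- rep(NA_real_, k)
  if (!is.null(TE)) {
    e <- .te_square(TE)
    if (nrow(e) != k)
      .stopf("energy matrix size (%d) does not match number of states (%d)",
             nrow(e), k)
    energy_to_reach <- vapply(seq_len(k),
                              function(j) mean(e[-j, j]), numeric(1))
  }
  out <- data.frame(
    state = labs,
    map_mean = colMeans(smat),
    map_sd = apply(smat, 2, stats::sd),
    cor_binary_degree = apply(smat, 2, sp_cor, v = nm$binary_degree),
    cor_strength = apply(smat, 2, sp_cor, v = nm$strength),
    cor_participation = apply(smat, 2, sp_cor, v = nm$participation),
    cor_hierarchy = apply(smat, 2, sp_cor, v = hierarchy_map),
    network_variance = apply(smat, 2, function(s)
      network_variance(omega, s)),
    energy_to_reach = energy_to_reach,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (anyNA(out[c("cor_binary_degree", "cor_strength", "cor_participation",
                  "cor_hierarchy")]))
    .warnf("constant predictor or state vector: some correlations are NA")
  out
}

#' Full predictor report: partial correlations and dominance analysis
#'
#' Runs \code{\link{state_predictor_table}}, then (a) partial Spearman
#' correlations of each state characterization against mean energy-to-reach,
#' partialling out each map's mean and (traditional) variance, and (b) a
#' dominance analysis with all five predictors together.
#'
#' @inheritParams state_predictor_table
#' @return List of class \code{predictor_report}: \code{table},
#'   \code{partials} (data frame), \code{dominance}.
#' @export
predictor_report <- function(states, conn, hierarchy_map, TE,
                             partition = NULL) {
  tab <- state_predictor_table(states, conn, hierarchy_map, TE, partition)
  preds <- c("cor_binary_degree", "cor_strength", "cor_participation",
             "cor_hierarchy", "network_variance")
  covar <- cbind(mean = tab$map_mean, variance = tab$map_sd^2)
  # maps whose mean and variance are comonotone (pure scale differences)
  # make the two covariates identical in rank; keep only the mean then
  if (qr(cbind(1, apply(covar, 2, rank)))$rank < 3) {
    .warnf("map mean and variance are rank-collinear; partialling out the mean only")
    covar <- covar[, "mean", drop = FALSE]
  }
  partials <- do.call(rbind, lapply(preds, function(pv) {
    ps <- partial_spearman(tab$energy_to_reach, tab[[pv]], covar)
    data.frame(predictor = pv, rho = ps$rho, p = ps$p,
               stringsAsFactors = FALSE)
  }))
  dom <- dominance_analysis(tab$energy_to_reach,
                            as.matrix(tab[preds]))
  structure(list(table = tab, partials = partials, dominance = dom),
            class = "predictor_report")
}
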