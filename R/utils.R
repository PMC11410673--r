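# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Seed handling: every stochastic entry point takes an explicit `seed`
# argument; NULL leaves the RNG state untouched.
.seed_rng <- function(seed) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

.check_square <- function(x, what = "matrix") {
  if (!is.matrix(x) || nrow(x) != ncol(x))
    .stopf("%s must be a square matrix (got %d x %d)", what,
           NROW(x), NCOL(x))
  invisible(x)
}

# Pairwise Euclidean distances between rows of a coordinate matrix.
.pairwise_dist <- function(coords) {
  as.matrix(stats::dist(coords))
}

# Upper-triangle edge list (i < j) of a symmetric weight matrix.
.edge_list <- function(w) {
  idx <- which(upper.tri(w) & w != 0, arr.ind = TRUE)
  data.frame(i = idx[, 1], j = idx[, 2], w = w[idx])
}

# Trapezoidal quadrature on a sampled function.
.trapz <- function(x, y) {
  m <- length(x)
  sum((y[-1] + y[-m]) / 2 * diff(x))
}

# Dense matrix exponential (Padé with scaling and squaring).
.expm <- function(m) as.matrix(Matrix::expm(m))
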