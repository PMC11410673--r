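# Tab-separated readers and writers. Matrix files carry a header row of
# labels; when written with row labels, the first column is named "label"
# and holds the row names.

#' Read a dense tab-separated matrix table
#'
#' @param path file path.
#' @param square_required error unless the matrix is square.
#' @return Numeric matrix with column labels (and row labels when the file
#'   carries a leading "label" column).
#' @export
read_matrix_table <- function(path, square_required = FALSE) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) != 1)
    .stopf("ragged rows in %s: field counts %s", path,
           paste(unique(nf), collapse = ", "))
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  has_rowlab <- names(df)[1] %in% c("label", "")
  rn <- NULL
  if (has_rowlab) {
    rn <- as.character(df[[1]])
    df <- df[-1]
  }
  bad <- !vapply(df, is.numeric, logical(1))
  if (any(bad))
    .stopf("non-numeric cells in %s (columns: %s)", path,
           paste(names(df)[bad], collapse = ", "))
  m <- as.matrix(df)
  rownames(m) <- rn
  if (square_required && nrow(m) != ncol(m))
    .stopf("square matrix required but %s is %d x %d", path, nrow(m), ncol(m))
  m
}

#' Write a matrix as a tab-separated table
#'
#' @param x matrix.
#' @param path file path.
#' @param row_labels write row names as a leading "label" column.
#' @export
write_matrix_table <- function(x, path, row_labels = !is.null(rownames(x))) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  # format at 17 significant digits so doubles round-trip exactly
  xf <- matrix(sprintf("%.17g", x), nrow(x), ncol(x),
               dimnames = dimnames(x))
  if (row_labels) {
    df <- data.frame(label = rownames(x) %||% paste0("V", seq_len(nrow(x))),
                     xf, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    utils::write.table(xf, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a region metadata table
#'
#' Expects tab-separated columns \code{label}, \code{hemisphere} (L/R),
#' \code{x}, \code{y}, \code{z} and optionally \code{sx}, \code{sy},
#' \code{sz} (unit-sphere centroids). The row order of this table is the
#' authoritative region order of a pipeline run.
#'
#' @param path file path.
#' @return List: \code{labels}, \code{hemisphere}, \code{coords3d},
#'   \code{sphere_coords} (or NULL), \code{module} (optional partition
#'   column, or NULL).
#' @export
read_region_table <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("label", "hemisphere", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    .stopf("region table %s lacks columns: %s", path,
           paste(miss, collapse = ", "))
  sphere <- NULL
  if (all(c("sx", "sy", "sz") %in% names(df)))
    sphere <- as.matrix(df[c("sx", "sy", "sz")])
  list(labels = as.character(df$label),
       hemisphere = as.character(df$hemisphere),
       coords3d = as.matrix(df[c("x", "y", "z")]),
       sphere_coords = sphere,
       module = if ("module" %in% names(df)) df$module else NULL)
}

#' Write a synthetic dataset to a directory in pipeline input formats
#'
#' Writes the connectome matrix, region table, state table and modulation
#' maps in the same tab-separated formats the readers consume, so the
#' pipeline runs unmodified on synthetic data.
#'
#' @param dataset a \code{synthetic_dataset}.
#' @param dir output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  conn <- dataset$connectome
  write_matrix_table(conn$weights, file.path(dir, "connectome.tsv"),
                     row_labels = FALSE)
  reg <- data.frame(label = conn$labels, hemisphere = conn$hemisphere,
                    x = conn$coords3d[, 1], y = conn$coords3d[, 2],
                    z = conn$coords3d[, 3],
                    sx = conn$sphere_coords[, 1],
                    sy = conn$sphere_coords[, 2],
                    sz = conn$sphere_coords[, 3],
                    module = dataset$partition)
  utils::write.table(reg, file.path(dir, "regions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  smat <- vapply(dataset$states, function(s) s$values, numeric(conn$n))
  colnames(smat) <- vapply(dataset$states, function(s) s$label, "")
  write_matrix_table(smat, file.path(dir, "states.tsv"), row_labels = FALSE)
  mmat <- cbind(receptor = dataset$modulation_maps$receptor$values,
                atrophy = dataset$modulation_maps$atrophy$values,
                hierarchy = dataset$hierarchy_map)
  write_matrix_table(mmat, file.path(dir, "maps.tsv"), row_labels = FALSE)
  invisible(dir)
}
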