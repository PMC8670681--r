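#' Spatial weight matrix
#'
#' Wraps an `N x N` matrix of nonnegative spatial weights with a zero
#' diagonal, the standard interaction structure of a spatial autoregressive
#' (SAR) model: unit `i`'s outcome depends on the weighted average
#' `sum_j w_ij y_jt` of the other units' outcomes.
#'
#' @param values Square numeric matrix of weights.
#' @param row_normalized Logical; whether every nonzero row sums to one.
#'   Detected from `values` when `NULL`.
#' @return An object of class `spatial_weights` with fields `values`,
#'   `n_units` and `row_normalized`.
#' @seealso [build_block_weights()], [validate_weights()]
#' @export
spatial_weights <- function(values, row_normalized = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("weights must be numeric")
  if (is.null(row_normalized)) {
    rs <- rowSums(values)
    nz <- rs[abs(rs) > 1e-12]
    row_normalized <- length(nz) > 0 && all(abs(nz - 1) < 1e-12) &&
      nrow(values) == ncol(values)
  }
  structure(list(values = values, n_units = nrow(values),
                 row_normalized = isTRUE(row_normalized)),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("spatial_weights: %d x %d, %srow-normalized\n",
              nrow(x$values), ncol(x$values),
              if (x$row_normalized) "" else "not "))
  viol <- validate_weights(x)
  if (length(viol)) cat("violations:", paste(viol, collapse = "; "), "\n")
  invisible(x)
}

#' Block-diagonal group-interaction weight matrix
#'
#' Builds the row-normalized group-interaction design: units are split into
#' groups of `block_size`; within a group every pair of distinct units gets
#' weight `1 / (block_size - 1)`, across groups the weight is zero.  Rows sum
#' to one, so the spectral radius is 1 and `I - rho * W` is invertible for
#' `|rho| < 1`.
#'
#' @param n_units Number of cross-sectional units; must be a positive
#'   multiple of `block_size`.
#' @param block_size Group size (default 10).
#' @return A [spatial_weights] object.
#' @examples
#' w <- build_block_weights(20)
#' all(abs(rowSums(w$values) - 1) < 1e-12)
#' @export
build_block_weights <- function(n_units, block_size = 10L) {
  block_size <- as.integer(block_size)
  if (block_size < 2L) stop("block_size must be at least 2")
  if (length(n_units) != 1L || is.na(n_units) || n_units < block_size ||
      n_units %% block_size != 0L) {
    stop(sprintf(
      "n_units must be a positive multiple of the block size (%d); got %s",
      block_size, format(n_units)))
  }
  block <- matrix(1 / (block_size - 1), block_size, block_size)
  diag(block) <- 0
  w <- kronecker(diag(n_units / block_size), block)
  spatial_weights(w, row_normalized = TRUE)
}

#' Validate a spatial weight matrix
#'
#' Checks the invariants a SAR weight matrix must satisfy: square shape, zero
#' diagonal, nonnegative entries, bounded row and column sums (bound 10), and
#' row normalization when claimed.  Violations are reported, not raised.
#'
#' @param w A [spatial_weights] object or plain matrix.
#' @param sum_bound Upper bound on absolute row and column sums (default 10).
#' @return Character vector of violation messages; empty if valid.
#' @export
validate_weights <- function(w, sum_bound = 10) {
  if (!inherits(w, "spatial_weights")) w <- spatial_weights(w)
  v <- w$values
  out <- character(0)
  if (nrow(v) != ncol(v)) {
    return("not square")
  }
  if (any(!is.finite(v))) out <- c(out, "non-finite weight")
  if (any(diag(v) != 0)) out <- c(out, "nonzero diagonal")
  if (any(v < 0, na.rm = TRUE)) out <- c(out, "negative weight")
  if (max(rowSums(abs(v))) > sum_bound) out <- c(out, "row sum exceeds bound")
  if (max(colSums(abs(v))) > sum_bound) out <- c(out, "column sum exceeds bound")
  if (w$row_normalized) {
    rs <- rowSums(v)
    nz <- rs[abs(rs) > 1e-12]
    if (any(abs(nz - 1) > 1e-12)) out <- c(out, "row not normalized")
  }
  out
}

#' Read a spatial weight matrix from disk
#'
#' Dense CSV (no header, `N` rows by `N` columns) or sparse matrix-market
#' (`.mtx`) files are supported; the format is detected from the file
#' extension.
#'
#' @param path File path ending in `.csv` (dense) or `.mtx` (sparse).
#' @return A [spatial_weights] object.
#' @export
read_weights <- function(path) {
  if (!file.exists(path)) stop("weights file not found: ", path)
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    m <- as.matrix(Matrix::readMM(path))
  } else {
    m <- as.matrix(read.csv(path, header = FALSE))
    dimnames(m) <- NULL
  }
  spatial_weights(m)
}

#' Write a spatial weight matrix to disk
#'
#' @param w A [spatial_weights] object.
#' @param path Destination; `.mtx` writes sparse matrix-market, anything else
#'   a dense headerless CSV.
#' @return `path`, invisibly.
#' @export
write_weights <- function(w, path) {
  if (!inherits(w, "spatial_weights")) w <- spatial_weights(w)
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    Matrix::writeMM(Matrix::Matrix(w$values, sparse = TRUE), path)
  } else {
    utils::write.table(w$values, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}
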