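#' Construct an in-memory chromatin contact matrix
#'
#' A dense, symmetric, non-negative n x n matrix of contact frequencies over
#' `n` uniform-width genomic bins — the in-memory equivalent of one
#' balanced-cooler chromosome block. Mild numeric asymmetry (below
#' `1e-6 * max(M)`) is repaired by averaging with the transpose; anything
#' larger is an error.
#'
#' @param bins Interval tibble of `n` uniform-width bins, in matrix order.
#' @param mat Numeric n x n matrix, non-negative.
#' @return An object of class `contact_matrix` with elements `bins`, `matrix`
#'   and `bin_bp` (the common bin width).
#' @export
contact_matrix <- function(bins, mat) {
  validate_intervals(bins, "bin")
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) abort("contact matrix must be square")
  if (nrow(mat) != nrow(bins)) {
    abort(sprintf("bin count (%d) does not match matrix dimension (%d)", nrow(bins), nrow(mat)))
  }
  if (any(!is.finite(mat))) abort("contact matrix has non-finite entries")
  if (any(mat < 0)) abort("contact matrix has negative entries")
  widths <- bins$end - bins$start
  if (length(unique(widths)) != 1L) abort("bins must have uniform width")
  asym <- max(abs(mat - t(mat)))
  if (asym > 0) {
    if (asym >= 1e-6 * max(mat)) {
      abort(sprintf("contact matrix asymmetry %.3g exceeds tolerance", asym))
    }
    mat <- (mat + t(mat)) / 2
  }
  dimnames(mat) <- NULL
  structure(
    list(bins = bins, matrix = mat, bin_bp = widths[1]),
    class = "contact_matrix"
  )
}

#' Read a dense contact matrix with its bin table
#'
#' The matrix is a tab-separated table of floats (row-major, no header); the
#' companion BED file gives the `n` uniform-width bins in row order.
#'
#' @param matrix_path TSV of the dense n x n matrix.
#' @param bins_path BED file of the n bins.
#' @return A [contact_matrix()].
#' @export
parse_contact_matrix <- function(matrix_path, bins_path) {
  bins <- parse_intervals(bins_path, "bed")
  mat <- as.matrix(utils::read.table(matrix_path, sep = "\t", header = FALSE))
  if (!is.numeric(mat)) abort("contact matrix TSV contains non-numeric entries")
  contact_matrix(bins, mat)
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf(
    "<contact_matrix> %d bins of %s bp on %s [%s, %s); mean contact %.3g\n",
    nrow(x$bins), format(x$bin_bp), x$bins$chrom[1],
    format_coord(min(x$bins$start)), format_coord(max(x$bins$end)),
    mean(x$matrix)
  ))
  invisible(x)
}

#' Write a contact matrix as dense TSV plus bin BED
#'
#' @param cm A [contact_matrix()].
#' @param matrix_path,bins_path Output paths.
#' @return `matrix_path`, invisibly.
#' @export
write_contact_matrix <- function(cm, matrix_path, bins_path) {
  utils::write.table(cm$matrix, matrix_path,
    sep = "\t", row.names = FALSE, col.names = FALSE
  )
  write_bed(cm$bins, bins_path)
  invisible(matrix_path)
}
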