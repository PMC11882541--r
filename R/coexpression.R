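# Marker-based cell classification and co-expression summaries for a
# cells x genes normalized expression matrix.

#' Read a cells-by-genes expression matrix
#'
#' TSV with cell ids in the first column and gene names as the header, or
#' MatrixMarket triplet (`.mtx`) with companion one-column cell and gene id
#' files.
#'
#' @param path TSV path, or MTX path when `cells_path`/`genes_path` given.
#' @param cells_path,genes_path Id files for MTX input (cells = rows).
#' @return Numeric matrix, rows = cells, columns = genes.
#' @export
read_expression_matrix <- function(path, cells_path = NULL, genes_path = NULL) {
  if (!is.null(cells_path)) {
    lines <- readLines(path)
    body <- lines[!startsWith(lines, "%")]
    parse_row <- function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    dims <- parse_row(body[1])
    mat <- matrix(0, dims[1], dims[2])
    if (length(body) > 1) {
      trip <- do.call(rbind, lapply(body[-1], parse_row))
      mat[trip[, 1:2, drop = FALSE]] <- trip[, 3]
    }
    rownames(mat) <- readLines(cells_path)
    colnames(mat) <- readLines(genes_path)
  } else {
    df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                            check.names = FALSE)
    mat <- as.matrix(df)
  }
  if (anyDuplicated(rownames(mat))) abort("duplicate cell ids")
  if (anyDuplicated(colnames(mat))) abort("duplicate gene ids")
  if (any(!is.finite(mat))) abort("non-finite expression values")
  mat
}

#' Classify cells by marker expression
#'
#' Cells with normalized marker expression strictly below `threshold` are
#' marker-negative; cells at or above it are marker-positive (a cell at
#' exactly the threshold is positive, since only "lower than" defines the
#' negative class).
#'
#' @param mat Cells x genes matrix (rownames = cell ids).
#' @param marker_gene Marker column name.
#' @param threshold Normalized-expression cutoff (default 0.5).
#' @return Tibble with `cell`, `expression`, `marker_positive`.
#' @export
classify_cells <- function(mat, marker_gene, threshold = 0.5) {
  if (!marker_gene %in% colnames(mat)) {
    abort(sprintf("marker gene '%s' absent from matrix", marker_gene))
  }
  expr <- mat[, marker_gene]
  tibble(
    cell = rownames(mat) %||% as.character(seq_len(nrow(mat))),
    expression = unname(expr),
    marker_positive = unname(expr >= threshold)
  )
}

#' Co-expression of candidate transcripts with a marker
#'
#' For each candidate gene, counts expressing cells (same threshold as the
#' marker), cells co-expressing marker and candidate, and the two
#' conditional fractions: of candidate-positive cells that are
#' marker-positive, and of marker-positive cells that are
#' candidate-positive.
#'
#' @inheritParams classify_cells
#' @param candidates Character vector of candidate gene names.
#' @return Tibble with one row per candidate: `gene`, `n_expressing`,
#'   `n_coexpressing`, `frac_candidate_pos_marker_pos`,
#'   `frac_marker_pos_candidate_pos`.
#' @export
coexpression_summary <- function(mat, marker_gene, candidates, threshold = 0.5) {
  if (!length(candidates)) abort("empty candidate list")
  miss <- setdiff(candidates, colnames(mat))
  if (length(miss)) abort(sprintf("candidate gene '%s' absent from matrix", miss[1]))
  marker_pos <- mat[, marker_gene] >= threshold
  n_marker <- sum(marker_pos)
  purrr::map_dfr(candidates, function(gene) {
    cand_pos <- mat[, gene] >= threshold
    co <- sum(cand_pos & marker_pos)
    tibble(
      gene = gene,
      n_expressing = sum(cand_pos),
      n_coexpressing = co,
      frac_candidate_pos_marker_pos = if (sum(cand_pos)) co / sum(cand_pos) else NA_real_,
      frac_marker_pos_candidate_pos = if (n_marker) co / n_marker else NA_real_
    )
  })
}
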