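# Shared interval arithmetic. All coordinates are 0-based half-open
# ([start, end)), BED-native; GFF3 is converted at the parsing boundary.

#' Construct a genomic interval tibble
#'
#' The package's interval currency: a tibble with columns `chrom`, `start`,
#' `end`, `strand`, `name`. Coordinates are 0-based half-open. `strand` is
#' one of `"+"`, `"-"`, `"."` (`"."` = unstranded).
#'
#' @param chrom Character vector of sequence names.
#' @param start,end Integer-ish base offsets, `0 <= start < end`.
#' @param strand Strand flags, recycled; default `"."`.
#' @param name Optional labels, recycled; default `NA`.
#' @return A tibble with one row per interval.
#' @examples
#' genomic_intervals("chr2", 100, 200, name = "peak1")
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".", name = NA_character_) {
  out <- tibble(
    chrom = as.character(chrom),
    start = as.double(start),
    end = as.double(end),
    strand = rep_len(as.character(strand), length(chrom)),
    name = rep_len(as.character(name), length(chrom))
  )
  validate_intervals(out)
  out
}

validate_intervals <- function(x, what = "interval") {
  if (!all(c("chrom", "start", "end") %in% names(x))) {
    abort(sprintf("%s table must have chrom/start/end columns", what))
  }
  if (any(is.na(x$chrom) | !nzchar(x$chrom))) {
    abort(sprintf("%s with empty chrom", what))
  }
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad)) {
    abort(sprintf(
      "%s %d violates 0 <= start < end (start=%s, end=%s)",
      what, bad[1], format(x$start[bad[1]]), format(x$end[bad[1]])
    ))
  }
  if ("strand" %in% names(x) && !all(x$strand %in% c("+", "-", "."))) {
    abort(sprintf("%s strand must be one of +, -, .", what))
  }
  invisible(x)
}

interval_midpoint <- function(x) (x$start + x$end) / 2

# For each row of `x`, total rows of `y` (same chrom) overlapping by >= min_bp.
count_overlaps <- function(x, y, min_bp = 1) {
  if (nrow(y) == 0L || nrow(x) == 0L) return(integer(nrow(x)))
  vapply(seq_len(nrow(x)), function(i) {
    same <- y$chrom == x$chrom[i]
    ov <- pmin(y$end[same], x$end[i]) - pmax(y$start[same], x$start[i])
    sum(ov >= min_bp)
  }, integer(1))
}

overlaps_any <- function(x, y, min_bp = 1) count_overlaps(x, y, min_bp) > 0L
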