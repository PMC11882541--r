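# Conservation calling from a pairwise alignment: windowed percent identity
# over reference bases, thresholded runs, then length/exon/blacklist filters.

#' Windowed percent-identity profile over reference bases
#'
#' For every non-gap reference base, the fraction of matching bases in a
#' `window_bp`-base window of *reference* bases centred there (shifted
#' inward at the sequence ends so every window holds exactly `window_bp`
#' reference bases). A gap or `N` in either sequence counts as a mismatch.
#'
#' @param aln_ref,aln_other Equal-length aligned strings (gap `-`), reference
#'   first.
#' @param window_bp Window size in reference bases.
#' @return A tibble with `ref_pos` (0-based reference offset) and `identity`
#'   in `[0, 1]`; one row per reference base.
#' @export
window_identity <- function(aln_ref, aln_other, window_bp = 100L) {
  if (nchar(aln_ref) != nchar(aln_other)) {
    abort("aligned sequences have unequal lengths")
  }
  if (window_bp < 1L) abort("window_bp must be >= 1")
  a <- strsplit(toupper(aln_ref), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(aln_other), "", fixed = TRUE)[[1]]
  is_ref <- a != "-"
  n_ref <- sum(is_ref)
  if (window_bp > n_ref) {
    abort(sprintf("window_bp (%d) exceeds reference length (%d)", window_bp, n_ref))
  }
  base <- c("A", "C", "G", "T")
  m <- as.numeric((a == b) & a %in% base)[is_ref]

  w <- as.integer(window_bp)
  cs <- c(0, cumsum(m))
  i <- seq_len(n_ref)
  s <- pmin(pmax(i - w %/% 2L, 1L), n_ref - w + 1L)
  identity <- (cs[s + w] - cs[s]) / w
  tibble(ref_pos = i - 1, identity = identity)
}

#' Call conserved regions from an identity profile
#'
#' Maximal runs of positions at or above `min_identity` become regions; runs
#' separated by fewer than `window_bp / 2` sub-threshold bases are merged so
#' one element is not fragmented into slivers. Region identity is the mean
#' profile value over the (merged) region.
#'
#' @param profile Output of [window_identity()].
#' @param min_identity Acceptance threshold (the screen uses 0.7: at least
#'   70% cross-species identity).
#' @param window_bp The window used to build the profile (sets the merge gap).
#' @param chrom Sequence name for the emitted intervals.
#' @return Tibble of conserved regions: `chrom`, `start`, `end`, `strand`,
#'   `name`, `identity`, `length_bp`; disjoint and sorted by `start`.
#' @export
call_conserved_regions <- function(profile, min_identity = 0.7, window_bp = 100L,
                                   chrom = "ref") {
  if (nrow(profile) == 0L) abort("empty identity profile")
  if (!(min_identity > 0 && min_identity <= 1)) abort("min_identity must be in (0, 1]")
  ok <- profile$identity >= min_identity
  if (!any(ok)) {
    return(conserved_tbl(chrom, double(), double(), double()))
  }
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- tibble(start = starts[r$values], end = ends[r$values]) # 1-based inclusive

  # merge runs separated by < window_bp / 2 below-threshold positions
  merged_s <- runs$start[1]
  merged_e <- runs$end[1]
  if (nrow(runs) > 1L) {
    for (k in 2:nrow(runs)) {
      if (runs$start[k] - merged_e[length(merged_e)] - 1L < window_bp / 2) {
        merged_e[length(merged_e)] <- runs$end[k]
      } else {
        merged_s <- c(merged_s, runs$start[k])
        merged_e <- c(merged_e, runs$end[k])
      }
    }
  }
  ident <- vapply(
    seq_along(merged_s),
    function(k) mean(profile$identity[merged_s[k]:merged_e[k]]),
    double(1)
  )
  conserved_tbl(
    chrom,
    profile$ref_pos[merged_s],
    profile$ref_pos[merged_e] + 1,
    ident
  )
}

conserved_tbl <- function(chrom, start, end, identity) {
  tibble(
    chrom = rep_len(chrom, length(start)),
    start = as.double(start), end = as.double(end),
    strand = rep_len(".", length(start)),
    name = if (length(start)) sprintf("cons_%03d", seq_along(start)) else character(),
    identity = as.double(identity),
    length_bp = as.double(end) - as.double(start)
  )
}

#' Filter conserved regions to screen candidates
#'
#' Drops regions overlapping an annotated exon or a blacklisted prior element
#' by one or more bases, and regions outside the closed length window
#' `[min_len, max_len]` (defaults 150 and 2100 bp, the size range of retained
#' candidates). Input order is preserved.
#'
#' @param regions Conserved-region tibble from [call_conserved_regions()].
#' @param exons,blacklist Interval tibbles (may be empty).
#' @param min_len,max_len Closed length bounds in bp.
#' @return The surviving rows of `regions`.
#' @export
filter_candidates <- function(regions, exons = NULL, blacklist = NULL,
                              min_len = 150, max_len = 2100) {
  empty <- tibble(chrom = character(), start = double(), end = double())
  exons <- exons %||% empty
  blacklist <- blacklist %||% empty
  keep <- regions$length_bp >= min_len & regions$length_bp <= max_len
  if (nrow(exons)) keep <- keep & !overlaps_any(regions, exons)
  if (nrow(blacklist)) keep <- keep & !overlaps_any(regions, blacklist)
  regions[keep, , drop = FALSE]
}

#' Write conserved regions as BED with identity in the score column
#'
#' Identity in `[0, 1]` is scaled to the BED score range 0–1000.
#'
#' @param regions Conserved-region tibble.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_conserved_bed <- function(regions, path) {
  x <- regions
  x$score <- round(1000 * x$identity)
  write_bed(x[, c("chrom", "start", "end", "name", "score", "strand")], path)
}
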