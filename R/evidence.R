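# Chromatin-mark evidence over conserved regions: count distinct active
# marks, veto on repressive marks, require a binding-site hit, and assign
# signed labels by promoter side and distance rank.

ACTIVE_MARKS <- c("H3K27ac", "H3K4me2", "p300", "RNAP2", "Med12")
REPRESSIVE_MARKS <- c("H3K27me3")

#' Count chromatin-mark evidence over regions
#'
#' A mark is "present" for a region iff at least one of its peaks overlaps
#' the region by one or more bases. Marks are counted as dataset types (one
#' vote per mark), not peak instances, so two H3K27ac peaks still count
#' once.
#'
#' @param regions Conserved-region tibble.
#' @param peak_tracks Named list of peak interval tibbles, one per mark.
#' @param active_marks,repressive_marks Mark-name sets (disjoint). Defaults
#'   are the screen's five activation-associated marks (H3K27ac, H3K4me2,
#'   p300, RNAP2, Med12) and H3K27me3 as the repressive mark.
#' @return `regions` with added columns `marks_present` (list of mark
#'   names), `n_active_marks`, `repressive_overlap`.
#' @export
count_marks <- function(regions, peak_tracks,
                        active_marks = ACTIVE_MARKS,
                        repressive_marks = REPRESSIVE_MARKS) {
  if (length(intersect(active_marks, repressive_marks))) {
    abort("active and repressive mark sets overlap")
  }
  known <- c(active_marks, repressive_marks)
  unknown <- setdiff(names(peak_tracks), known)
  if (length(unknown)) {
    abort(sprintf("unknown mark name in tracks: %s", unknown[1]))
  }
  present <- lapply(names(peak_tracks), function(mk) {
    overlaps_any(regions, peak_tracks[[mk]])
  })
  names(present) <- names(peak_tracks)
  marks_present <- lapply(seq_len(nrow(regions)), function(i) {
    names(present)[vapply(present, `[`, logical(1), i)]
  })
  regions$marks_present <- marks_present
  regions$n_active_marks <- vapply(
    marks_present, function(m) length(intersect(m, active_marks)), integer(1)
  )
  regions$repressive_overlap <- vapply(
    marks_present, function(m) length(intersect(m, repressive_marks)) > 0L, logical(1)
  )
  regions
}

#' Classify regions as candidate cis-regulatory modules
#'
#' A region passes the screen iff it carries at least `min_marks` distinct
#' activation-associated marks, is not touched by a repressive mark, and
#' holds at least one predicted binding site. Regions with two or fewer
#' active marks, or any repressive overlap, are rejected.
#'
#' @param profile Tibble with columns `n_active_marks`, `repressive_overlap`
#'   and `has_tfbs` (from [count_marks()] plus a binding-site flag).
#' @param min_marks Minimum distinct active marks (default 3).
#' @return Logical vector, one per row.
#' @export
classify_pcrm <- function(profile, min_marks = 3L) {
  need <- c("n_active_marks", "repressive_overlap", "has_tfbs")
  miss <- setdiff(need, names(profile))
  if (length(miss)) abort(sprintf("profile lacks column '%s'", miss[1]))
  profile$n_active_marks >= min_marks &
    !profile$repressive_overlap &
    profile$has_tfbs
}

#' Assign signed distance-rank labels relative to a promoter
#'
#' Candidates upstream of the promoter (by gene strand) get negative labels,
#' downstream positive; each side is numbered 1..k by increasing midpoint
#' distance from the promoter midpoint, nearest first, ties broken by start
#' coordinate.
#'
#' @param candidates Candidate tibble (intervals).
#' @param promoter One-row interval tibble (e.g. TSS +/- 500 bp).
#' @param gene_strand `"+"` or `"-"`; upstream means lower coordinates for
#'   `"+"` genes, higher for `"-"`.
#' @return `candidates` with columns `distance_to_promoter_bp` and `label`
#'   (signed non-zero integer), sorted by label side then rank.
#' @export
label_pcrms <- function(candidates, promoter, gene_strand = "+") {
  if (!gene_strand %in% c("+", "-")) abort("gene_strand must be '+' or '-'")
  if (nrow(candidates) == 0L) {
    candidates$distance_to_promoter_bp <- double()
    candidates$label <- integer()
    return(candidates)
  }
  if (any(candidates$chrom != promoter$chrom[1])) {
    abort("candidates and promoter on different chrom")
  }
  ov <- overlaps_any(candidates, promoter)
  if (any(ov)) {
    abort(sprintf(
      "candidate [%s, %s) overlaps the promoter; side is ambiguous",
      format_coord(candidates$start[which(ov)[1]]), format_coord(candidates$end[which(ov)[1]])
    ))
  }
  pm <- interval_midpoint(promoter)[1]
  mid <- interval_midpoint(candidates)
  upstream <- if (gene_strand == "+") mid < pm else mid > pm
  dist <- abs(mid - pm)
  candidates$distance_to_promoter_bp <- dist
  lab <- integer(nrow(candidates))
  for (side in c(TRUE, FALSE)) {
    i <- which(upstream == side)
    if (!length(i)) next
    r <- order(dist[i], candidates$start[i])
    lab[i[r]] <- seq_along(i) * (if (side) -1L else 1L)
  }
  candidates$label <- lab
  dplyr::arrange(candidates, .data$label < 0, abs(.data$label))
}
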