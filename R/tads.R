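# Insulation-score TAD calling. A boundary is a bin whose surrounding
# square window of cross-contacts is depleted: we compute the mean contact
# in an off-diagonal w x w window at several depths (scales), average the
# scales, and accept local minima that pass a prominence filter (delta) and
# a rank-sum comparison of intra-domain versus cross-boundary contacts at
# the stated significance threshold (Bonferroni-corrected over candidates,
# the semantics the hicFindTADs tool attaches to its threshold).

#' Multi-scale insulation profile of a contact matrix
#'
#' For each bin `i` and depth `d`, the score is the mean of the square
#' submatrix `M[i-w .. i-1, i+1 .. i+w]` with `w = d %/% bin_bp` — the
#' contacts crossing bin `i` up to depth `d`. Depths are `n_scales` evenly
#' spaced bin multiples between `min_depth_bp` and `max_depth_bp` (defaults
#' 3000 and 31500 bp). Bins where the window leaves the matrix are
#' undefined (`NA`).
#'
#' @param cm A [contact_matrix()].
#' @param min_depth_bp,max_depth_bp Depth range in bp.
#' @param n_scales Number of depths.
#' @return An object of class `insulation_profile`: a list with `profile`
#'   (tibble: `bin`, `w_bins`, `depth_bp`, `score`), `scales` (window sizes
#'   in bins), and the source `cm`.
#' @export
insulation_profile <- function(cm, min_depth_bp = 3000, max_depth_bp = 31500,
                               n_scales = 3L) {
  bw <- cm$bin_bp
  if (min_depth_bp < bw) {
    abort(sprintf("min_depth_bp (%s) below bin width (%s)", min_depth_bp, bw))
  }
  if (max_depth_bp < min_depth_bp) abort("max_depth_bp < min_depth_bp")
  w_min <- max(1L, min_depth_bp %/% bw)
  w_max <- max(w_min, max_depth_bp %/% bw)
  ws <- unique(round(seq(w_min, w_max, length.out = n_scales)))
  n <- nrow(cm$matrix)
  M <- cm$matrix
  prof <- purrr::map_dfr(ws, function(w) {
    score <- rep(NA_real_, n)
    lo <- w + 1L
    hi <- n - w
    if (lo <= hi) {
      for (i in lo:hi) {
        score[i] <- mean(M[(i - w):(i - 1L), (i + 1L):(i + w)])
      }
    }
    tibble(bin = seq_len(n), w_bins = w, depth_bp = w * bw, score = score)
  })
  structure(
    list(profile = prof, scales = ws, cm = cm),
    class = "insulation_profile"
  )
}

#' @export
print.insulation_profile <- function(x, ...) {
  cat(sprintf(
    "<insulation_profile> %d bins, scales %s bins (%s bp)\n",
    nrow(x$cm$bins), paste(x$scales, collapse = "/"),
    paste(x$scales * x$cm$bin_bp, collapse = "/")
  ))
  invisible(x)
}

# Scale-averaged, lightly smoothed insulation; NA outside the common
# defined range. Smoothing is a centred 3-bin running mean, which removes
# single-bin noise wiggles without moving minima.
averaged_insulation <- function(ins, smooth = 3L) {
  wide <- tidyr::pivot_wider(ins$profile,
    id_cols = "bin", names_from = "w_bins", values_from = "score"
  )
  avg <- rowMeans(as.matrix(wide[, -1, drop = FALSE]))
  if (smooth > 1L) {
    k <- rep(1 / smooth, smooth)
    sm <- stats::filter(avg, k, sides = 2)
    avg <- as.numeric(sm)
  }
  avg
}

#' Call TAD boundaries and domains from an insulation profile
#'
#' Candidate boundaries are local minima of the scale-averaged insulation
#' (minimum within +/- w_min bins). A candidate is accepted iff (a) its
#' prominence on the min-max normalized profile — the smaller of the rises
#' to the highest profile value between it and the neighbouring candidate
#' (or profile edge) on each side — is at least `delta`, and (b) the
#' one-sided rank-sum test of intra-domain contacts against cross-boundary
#' contacts is significant at every scale after Bonferroni correction over
#' candidates (`p * n_candidates < threshold`). Domains tile the matrix
#' span between consecutive accepted boundaries; a boundary bin belongs to
#' the downstream domain.
#'
#' @param ins An [insulation_profile()].
#' @param threshold Rank-sum significance level (default 0.05).
#' @param delta Minimum normalized prominence (default 0.01).
#' @return An object of class `tad_set`: `boundaries` (bin indices),
#'   `boundary_bp` (genomic positions of boundary bin starts), `domains`
#'   (interval tibble tiling the span), `params`, `bins`.
#' @export
call_tads <- function(ins, threshold = 0.05, delta = 0.01) {
  bins <- ins$cm$bins
  n <- nrow(bins)
  avg <- averaged_insulation(ins)
  def <- which(!is.na(avg))
  if (!length(def)) abort("insulation profile entirely undefined")
  params <- list(
    threshold = threshold, delta = delta,
    min_depth_bp = min(ins$scales) * ins$cm$bin_bp,
    max_depth_bp = max(ins$scales) * ins$cm$bin_bp
  )
  rng <- range(avg[def])
  span <- tibble(
    chrom = bins$chrom[1], start = bins$start[1], end = bins$end[n],
    strand = ".", name = "domain_001"
  )
  if (rng[2] - rng[1] <= 0) {
    return(new_tad_set(integer(), bins, span, params))
  }
  norm <- (avg - rng[1]) / (rng[2] - rng[1])

  ord <- min(ins$scales)
  is_cand <- vapply(def, function(i) {
    wnd <- norm[max(min(def), i - ord):min(max(def), i + ord)]
    norm[i] == min(wnd) && norm[i] < max(wnd)
  }, logical(1))
  cand <- def[is_cand]
  # collapse candidates closer than ord bins (tied plateaus) to the deepest
  if (length(cand) > 1L) {
    grp <- cumsum(c(1L, diff(cand) > ord))
    cand <- vapply(split(cand, grp), function(g) g[which.min(norm[g])], integer(1))
    cand <- unname(sort(cand))
  }
  if (!length(cand)) {
    return(new_tad_set(integer(), bins, span, params))
  }

  # prominence against the highest profile point between neighbouring
  # candidates (or the defined edge)
  fences <- c(min(def), cand, max(def))
  prom <- vapply(seq_along(cand), function(k) {
    i <- cand[k]
    left_max <- max(norm[fences[k]:i], na.rm = TRUE)
    right_max <- max(norm[i:fences[k + 2L]], na.rm = TRUE)
    min(left_max, right_max) - norm[i]
  }, double(1))

  keep <- prom >= delta
  cand2 <- cand[keep]
  if (!length(cand2)) {
    return(new_tad_set(integer(), bins, span, params))
  }

  # Rank-sum acceptance: intra-domain vs cross-boundary contacts at every
  # scale, Bonferroni-corrected over candidates. Test windows are clipped
  # at the neighbouring candidate boundaries so the samples describe the
  # putative flanking domains only — otherwise a mid-domain bin whose
  # window spans a real boundary inherits its contrast and tests
  # significant for the wrong reason.
  M <- ins$cm$matrix
  nb_prev <- c(min(def) - 1L, cand2[-length(cand2)])
  nb_next <- c(cand2[-1L], max(def) + 1L)
  pmax_scale <- vapply(seq_along(cand2), function(k) {
    b <- cand2[k]
    w_cap <- min(b - nb_prev[k], nb_next[k] - b, b - 1L, n - b)
    ps <- vapply(ins$scales, function(w) {
      w <- min(w, w_cap)
      if (w < 2L) return(1)
      left <- M[(b - w):(b - 1L), (b - w):(b - 1L)]
      right <- M[(b + 1L):(b + w), (b + 1L):(b + w)]
      intra <- c(left[upper.tri(left)], right[upper.tri(right)])
      cross <- as.numeric(M[(b - w):(b - 1L), (b + 1L):(b + w)])
      suppressWarnings(
        wilcox.test(intra, cross, alternative = "greater", exact = FALSE)$p.value
      )
    }, double(1))
    max(ps)
  }, double(1))

  accepted <- cand2[pmax_scale * length(cand2) < threshold]
  if (!length(accepted)) {
    return(new_tad_set(integer(), bins, span, params))
  }
  cuts <- bins$start[accepted]
  edges <- c(bins$start[1], cuts, bins$end[n])
  domains <- tibble(
    chrom = bins$chrom[1],
    start = edges[-length(edges)],
    end = edges[-1],
    strand = ".",
    name = sprintf("domain_%03d", seq_len(length(edges) - 1L))
  )
  new_tad_set(accepted, bins, domains, params)
}

new_tad_set <- function(boundaries, bins, domains, params) {
  structure(
    list(
      boundaries = as.integer(boundaries),
      boundary_bp = bins$start[boundaries],
      domains = domains,
      params = params,
      bins = bins
    ),
    class = "tad_set"
  )
}

#' @export
print.tad_set <- function(x, ...) {
  cat(sprintf(
    "<tad_set> %d boundaries, %d domains over [%s, %s)\n",
    length(x$boundaries), nrow(x$domains),
    format_coord(min(x$domains$start)), format_coord(max(x$domains$end))
  ))
  invisible(x)
}

#' Fraction of TAD boundaries near a CTCF peak
#'
#' A boundary is concordant if its bin midpoint lies within `tol_bp` of the
#' midpoint of any CTCF peak. With no boundaries the concordance is
#' undefined and `NA` is returned (not 0).
#'
#' @param tads A [call_tads()] result.
#' @param ctcf_peaks CTCF peak interval tibble.
#' @param tol_bp Distance tolerance in bp.
#' @return Fraction in `[0, 1]`, or `NA` if there are no boundaries.
#' @export
boundary_ctcf_concordance <- function(tads, ctcf_peaks, tol_bp = 10000) {
  if (!length(tads$boundaries)) return(NA_real_)
  if (nrow(ctcf_peaks) == 0L) return(0)
  bmid <- (tads$bins$start[tads$boundaries] + tads$bins$end[tads$boundaries]) / 2
  pmid <- interval_midpoint(ctcf_peaks)
  mean(vapply(bmid, function(m) any(abs(pmid - m) <= tol_bp), logical(1)))
}

#' Do two intervals share a TAD?
#'
#' Midpoint-based: `TRUE` iff both interval midpoints fall in the same
#' domain. Domains are half-open, so a midpoint exactly on a boundary
#' belongs to the downstream domain.
#'
#' @param a,b One-row interval tibbles.
#' @param tads A [call_tads()] result.
#' @return Logical scalar.
#' @export
same_tad <- function(a, b, tads) {
  domain_index(interval_midpoint(a)[1], tads) ==
    domain_index(interval_midpoint(b)[1], tads)
}

domain_index <- function(pos, tads) {
  d <- tads$domains
  i <- which(pos >= d$start & pos < d$end)
  if (!length(i)) {
    abort(sprintf("position %s outside the matrix span", format_coord(pos)))
  }
  i[1]
}

#' Is a region accessible (overlapping an ATAC peak)?
#'
#' @param regions Interval tibble.
#' @param atac_peaks ATAC peak interval tibble.
#' @param min_overlap_bp Minimum overlap in bp (default 1).
#' @return Logical vector, one per region.
#' @export
is_accessible <- function(regions, atac_peaks, min_overlap_bp = 1) {
  overlaps_any(regions, atac_peaks, min_bp = min_overlap_bp)
}

#' Write TAD boundaries and domains as BED
#'
#' @param tads A [call_tads()] result.
#' @param boundaries_path,domains_path Output BED paths.
#' @return `domains_path`, invisibly.
#' @export
write_tads_bed <- function(tads, boundaries_path, domains_path) {
  b <- tads$bins[tads$boundaries, , drop = FALSE]
  if (nrow(b)) b$name <- sprintf("boundary_%03d", seq_len(nrow(b)))
  write_bed(b, boundaries_path)
  write_bed(tads$domains, domains_path)
  invisible(domains_path)
}
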