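# Position-weight-matrix scoring with exact score-distribution p-values.
#
# Scores are log2 odds against a background base composition. The null
# score distribution is computed exactly by convolving the four-valued
# per-column score distributions after rounding every column score to a
# multiple of `granularity` bits; the rounding error of any word score is
# therefore bounded by L * granularity / 2. Scanning uses the same rounded
# units, so scan p-values agree exactly with the distribution.

BASES <- c("A", "C", "G", "T")

#' Build a log-odds PWM from a count matrix
#'
#' @param counts 4 x L non-negative matrix of base counts, rows A, C, G, T.
#' @param background Base probabilities (A, C, G, T), summing to 1, all > 0.
#' @param pseudocount Total pseudocount, split across bases in proportion to
#'   the background (0.8 by default, common JASPAR practice).
#' @param name Motif name.
#' @return An object of class `pwm` with elements `name`, `counts`,
#'   `log_odds`, `background`, `pseudocount`, `length`.
#' @export
pwm_from_counts <- function(counts, background = rep(0.25, 4), pseudocount = 0.8,
                            name = "pwm") {
  counts <- as.matrix(counts)
  if (length(counts) == 0L || ncol(counts) < 1L || nrow(counts) != 4L) {
    abort("counts must be a 4 x L matrix with L >= 1")
  }
  if (any(counts < 0)) abort("negative motif counts")
  if (any(colSums(counts) == 0)) abort("all-zero count column")
  if (length(background) != 4L || any(background <= 0)) {
    abort("background must be 4 positive probabilities")
  }
  background <- background / sum(background)
  if (pseudocount <= 0) abort("pseudocount must be > 0")
  rownames(counts) <- BASES
  csum <- rep(colSums(counts), each = 4L)
  prob <- (counts + pseudocount * background) / (csum + pseudocount)
  lo <- log2(prob / background)
  structure(
    list(
      name = name, counts = counts, log_odds = lo,
      background = setNames(background, BASES),
      pseudocount = pseudocount, length = ncol(counts)
    ),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf(
    "<pwm> %s: %d columns, consensus %s, max score %.2f bits\n",
    x$name, x$length, pwm_consensus(x), sum(apply(x$log_odds, 2, max))
  ))
  invisible(x)
}

#' Consensus sequence of a PWM (highest-count base per column)
#' @param pwm A [pwm_from_counts()] object.
#' @return A string of length `pwm$length`.
#' @export
pwm_consensus <- function(pwm) {
  paste(BASES[apply(pwm$counts, 2, which.max)], collapse = "")
}

#' Read JASPAR PFM flat files
#'
#' Accepts the JASPAR flat format: a `>ID NAME` header followed by four rows
#' of integer counts (A, C, G, T), with or without the `A [ ... ]` bracket
#' decoration. Several motifs per file are allowed.
#'
#' @param path PFM file.
#' @inheritParams pwm_from_counts
#' @return A named list of `pwm` objects.
#' @export
read_jaspar_pfm <- function(path, background = rep(0.25, 4), pseudocount = 0.8) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- which(startsWith(lines, ">"))
  if (!length(heads)) abort("no '>' headers in PFM file")
  out <- lapply(seq_along(heads), function(k) {
    from <- heads[k] + 1L
    to <- if (k < length(heads)) heads[k + 1L] - 1L else length(lines)
    body <- lines[from:to]
    if (length(body) != 4L) {
      abort(sprintf("motif '%s': expected 4 count rows, got %d", lines[heads[k]], length(body)))
    }
    rows <- lapply(body, function(l) {
      l <- gsub("^[ACGTacgt]\\s*\\[?|\\]\\s*$", "", trimws(l))
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    if (length(unique(lengths(rows))) != 1L) {
      abort(sprintf("motif '%s': ragged count rows", lines[heads[k]]))
    }
    counts <- do.call(rbind, rows)
    nm <- trimws(sub("^>", "", lines[heads[k]]))
    nm <- strsplit(nm, "\\s+")[[1]]
    nm <- if (length(nm) >= 2) nm[2] else nm[1]
    pwm_from_counts(counts, background, pseudocount, name = nm)
  })
  setNames(out, vapply(out, `[[`, character(1), "name"))
}

# Rounded per-column score units (4 x L integer matrix).
pwm_units <- function(pwm, granularity) {
  if (granularity <= 0) abort("granularity must be > 0")
  round(pwm$log_odds / granularity)
}

#' Exact null distribution of the PWM score
#'
#' Position-wise convolution of the per-column score distributions under the
#' background, after rounding column scores to multiples of `granularity`
#' bits. Exact up to that rounding — no sampling, no normal approximation.
#'
#' @inheritParams pwm_consensus
#' @param granularity Score rounding step in bits.
#' @return A list with `units` (integer score values, ascending), `prob`
#'   (their probabilities), `tail` (P(score >= unit)), `granularity`.
#' @export
pwm_score_distribution <- function(pwm, granularity = 0.01) {
  u <- pwm_units(pwm, granularity)
  lo_min <- sum(apply(u, 2, min))
  lo_max <- sum(apply(u, 2, max))
  if (lo_max == lo_min) {
    abort("score distribution collapses to a single atom; granularity too coarse for this PWM")
  }
  # dp over integer score offsets, probabilities indexed lo_min..lo_max
  dp <- c(1)
  dp_min <- 0L
  for (j in seq_len(ncol(u))) {
    cmin <- min(u[, j])
    span <- max(u[, j]) - cmin
    new <- numeric(length(dp) + span)
    for (b in 1:4) {
      off <- u[b, j] - cmin
      idx <- seq_along(dp) + off
      new[idx] <- new[idx] + dp * pwm$background[b]
    }
    dp <- new
    dp_min <- dp_min + cmin
  }
  units <- dp_min + seq_along(dp) - 1L
  keep <- dp > 0
  units <- units[keep]
  prob <- dp[keep]
  tail <- rev(cumsum(rev(prob)))
  list(units = units, prob = prob, tail = pmin(tail, 1), granularity = granularity)
}

# P(score >= s) against a distribution from pwm_score_distribution().
dist_pvalue <- function(dist, score_units) {
  vapply(score_units, function(su) {
    i <- which(dist$units >= su)
    if (!length(i)) 0 else dist$tail[i[1]]
  }, double(1))
}

#' Score threshold for a target tail probability
#'
#' Returns the smallest representable score `s*` (a multiple of
#' `granularity`) with `P(score >= s*) <= alpha` under the exact background
#' distribution, together with a `pvalue_of()` lookup.
#'
#' @inheritParams pwm_score_distribution
#' @param alpha Target tail probability, in (0, 1].
#' @return A list with `threshold` (bits), `tail_prob` (achieved tail mass),
#'   `alpha`, `granularity`, and `pvalue_of`, a function mapping a score in
#'   bits to `P(score >= x)`.
#' @export
exact_pvalue_threshold <- function(pwm, alpha = 0.01, granularity = 0.01) {
  if (!(alpha > 0 && alpha <= 1)) abort("alpha must be in (0, 1]")
  dist <- pwm_score_distribution(pwm, granularity)
  ok <- which(dist$tail <= alpha)
  if (!length(ok)) {
    # tail at the maximum atom still exceeds alpha: no representable score
    # has tail <= alpha except above the support
    s_star <- (max(dist$units) + 1L) * granularity
  } else {
    s_star <- dist$units[ok[1]] * granularity
  }
  list(
    threshold = s_star,
    tail_prob = if (length(ok)) dist$tail[ok[1]] else 0,
    alpha = alpha,
    granularity = granularity,
    pvalue_of = function(score) {
      dist_pvalue(dist, ceiling(score / granularity - 1e-9))
    }
  )
}

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Scan a sequence for PWM hits on both strands
#'
#' Every length-L window is scored forward (+ strand) and as its reverse
#' complement (- strand); windows containing `N` are skipped. A hit is a
#' window whose exact background p-value is below `alpha`. Hit intervals are
#' always reported in reference coordinates (the matched window), with the
#' strand flag carrying orientation.
#'
#' @param seq A sequence string, or a one-row tibble from [parse_fasta()].
#' @param pwm A `pwm` object.
#' @param alpha Per-window p-value cutoff (default 1e-2, the screen's motif
#'   evidence cutoff).
#' @param granularity Score rounding step in bits.
#' @param chrom Sequence name for the hit intervals.
#' @return Tibble of hits: `pwm`, `chrom`, `start`, `end`, `strand`, `score`
#'   (bits, rounded to `granularity`), `pvalue`; sorted by `start` then
#'   strand (`+` before `-`).
#' @export
scan_sequence <- function(seq, pwm, alpha = 0.01, granularity = 0.01, chrom = NULL) {
  if (is.data.frame(seq)) {
    chrom <- chrom %||% seq$id[1]
    seq <- seq$seq[1]
  }
  chrom <- chrom %||% "seq"
  seq <- toupper(seq)
  L <- pwm$length
  empty <- tibble(
    pwm = character(), chrom = character(), start = double(), end = double(),
    strand = character(), score = double(), pvalue = double()
  )
  n <- nchar(seq)
  if (n < L) return(empty)

  dist <- pwm_score_distribution(pwm, granularity)
  u <- pwm_units(pwm, granularity)
  code <- match(strsplit(seq, "", fixed = TRUE)[[1]], BASES) # NA for N etc.
  nw <- n - L + 1L
  fwd <- numeric(nw)
  rev_ <- numeric(nw)
  valid <- rep(TRUE, nw)
  for (j in seq_len(L)) {
    cj <- code[j:(j + nw - 1L)]
    valid <- valid & !is.na(cj)
    cj[is.na(cj)] <- 1L
    fwd <- fwd + u[cj, j]
    # reverse complement: window position j pairs with pwm column L-j+1,
    # complemented base 5 - code
    rev_ <- rev_ + u[5L - cj, L - j + 1L]
  }
  fwd <- unname(fwd)
  rev_ <- unname(rev_)
  ps_f <- dist_pvalue(dist, fwd)
  ps_r <- dist_pvalue(dist, rev_)
  hit_f <- valid & ps_f < alpha
  hit_r <- valid & ps_r < alpha
  out <- dplyr::bind_rows(
    tibble(
      pwm = pwm$name, chrom = chrom, start = which(hit_f) - 1,
      end = which(hit_f) - 1 + L, strand = "+",
      score = fwd[hit_f] * granularity, pvalue = ps_f[hit_f]
    ),
    tibble(
      pwm = pwm$name, chrom = chrom, start = which(hit_r) - 1,
      end = which(hit_r) - 1 + L, strand = "-",
      score = rev_[hit_r] * granularity, pvalue = ps_r[hit_r]
    )
  )
  if (!nrow(out)) return(empty)
  dplyr::arrange(out, .data$start, .data$strand)
}

#' Scan with several PWMs at once
#'
#' @inheritParams scan_sequence
#' @param pwms A list of `pwm` objects (e.g. from [read_jaspar_pfm()]).
#' @return Row-bound hit tibble across motifs.
#' @export
scan_sequence_set <- function(seq, pwms, alpha = 0.01, granularity = 0.01, chrom = NULL) {
  purrr::map_dfr(pwms, scan_sequence,
    seq = seq, alpha = alpha,
    granularity = granularity, chrom = chrom
  )
}

#' Write motif hits as BED6
#'
#' The BED score column is `round(-10 * log10(pvalue))`, capped at 1000.
#'
#' @param hits Hit tibble from [scan_sequence()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, path) {
  x <- tibble(
    chrom = hits$chrom, start = hits$start, end = hits$end,
    name = hits$pwm,
    score = pmin(1000, round(-10 * log10(pmax(hits$pvalue, 1e-100)))),
    strand = hits$strand
  )
  write_bed(x, path)
}

IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Match a window against an IUPAC core motif
#'
#' `TRUE` iff every base of `window` belongs to the degenerate class at the
#' corresponding core position (e.g. `S` = C or G). Used for the core
#' binding-site sequences targeted by disruption mutagenesis (Ets `GGAA`,
#' Tcf/Lef `SCTTTGATS`, homeodomain `TAATTA`).
#'
#' @param window Sequence window, same length as the core.
#' @param core IUPAC string.
#' @return Logical scalar.
#' @export
matches_core <- function(window, core) {
  window <- toupper(window)
  core <- toupper(core)
  if (nchar(window) != nchar(core)) {
    abort(sprintf("window length %d != core length %d", nchar(window), nchar(core)))
  }
  cw <- strsplit(window, "", fixed = TRUE)[[1]]
  cc <- strsplit(core, "", fixed = TRUE)[[1]]
  if (!all(cc %in% names(IUPAC))) {
    abort(sprintf("invalid IUPAC code '%s' in core", setdiff(cc, names(IUPAC))[1]))
  }
  all(vapply(seq_along(cc), function(i) cw[i] %in% IUPAC[[cc[i]]], logical(1)))
}

# 0-based offsets of all core matches within seq (forward strand).
core_match_offsets <- function(seq, core) {
  k <- nchar(core)
  n <- nchar(seq)
  if (n < k) return(integer())
  starts <- 0:(n - k)
  starts[vapply(starts, function(s) matches_core(substr(seq, s + 1, s + k), core), logical(1))]
}
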