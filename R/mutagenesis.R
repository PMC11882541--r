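# Substitution-only disruption of a core binding site: overwrite the core
# with a restriction-enzyme recognition sequence using as few base
# substitutions as possible, verify that the core is destroyed and that the
# edit creates no new predicted binding sites.

#' Design a restriction-site disruption of a core binding site
#'
#' Tries every placement of every catalog enzyme recognition sequence
#' (IUPAC allowed) that overlaps the core match inside the target hit
#' window, realizing each placement with substitutions only (at degenerate
#' enzyme positions the lexicographically smallest compatible base is
#' chosen, keeping the reference base where it already complies). Among
#' placements that destroy the core — no core match remains at any offset
#' overlapping the original core — the one with the fewest substitutions
#' wins, ties resolved by leftmost placement then catalog order. If
#' `pwms` is supplied, the edit is re-scanned and gained/lost hits at
#' `alpha` recorded.
#'
#' @param seq Wild-type sequence string.
#' @param hit One-row hit tibble (`start`, `end`, 0-based half-open in
#'   `seq`) locating the binding site to disrupt.
#' @param core IUPAC core string that must be present in the hit window
#'   (e.g. `"GGAA"`, `"SCTTTGATS"`, `"TAATTA"`).
#' @param enzymes Named character vector of recognition sequences (IUPAC),
#'   e.g. `c(BamHI = "GGATCC")`.
#' @param max_subs Maximum substitutions allowed (plan fails otherwise).
#' @param pwms Optional list of `pwm` objects for the no-gain re-scan.
#' @param alpha Re-scan p-value cutoff (1e-2, the discovery cutoff).
#' @return An object of class `mutagenesis_plan`. `plan$feasible` is
#'   `FALSE` (failure sentinel) when no placement within `max_subs`
#'   substitutions destroys the core; otherwise the plan carries
#'   `substitutions` (tibble: `offset`, `ref_base`, `alt_base`),
#'   `mutated_sequence`, `enzyme`, `placement`, `lost_core`, `gained_hits`,
#'   `lost_hits` and `accepted`.
#' @export
design_core_disruption <- function(seq, hit, core, enzymes, max_subs = 4L,
                                   pwms = NULL, alpha = 0.01) {
  seq <- toupper(seq)
  if (is.null(names(enzymes)) || !length(enzymes)) {
    abort("enzymes must be a non-empty named character vector")
  }
  if (max_subs < 0L) abort("max_subs must be >= 0")
  win_start <- hit$start[1]
  win_end <- hit$end[1]
  window <- substr(seq, win_start + 1, win_end)
  k <- nchar(core)
  offs <- core_match_offsets(window, core)
  if (!length(offs)) {
    abort("hit window contains no match to the core; nothing to disrupt")
  }
  core_start <- win_start + offs[1]
  core_end <- core_start + k

  cand <- list()
  for (e in seq_along(enzymes)) {
    site <- toupper(enzymes[[e]])
    le <- nchar(site)
    if (le > nchar(seq)) abort(sprintf("enzyme site '%s' longer than sequence", site))
    site_chars <- strsplit(site, "", fixed = TRUE)[[1]]
    if (!all(site_chars %in% names(IUPAC))) {
      abort(sprintf("enzyme '%s' has a non-IUPAC character", names(enzymes)[e]))
    }
    p_lo <- max(0L, core_start - le + 1L)
    p_hi <- min(nchar(seq) - le, core_end - 1L)
    if (p_lo > p_hi) next
    for (p in p_lo:p_hi) {
      mut <- seq
      subs <- list()
      ok <- TRUE
      for (j in seq_len(le)) {
        pos <- p + j # 1-based
        ref <- substr(seq, pos, pos)
        allowed <- IUPAC[[site_chars[j]]]
        if (ref %in% allowed) next
        alt <- allowed[1]
        substr(mut, pos, pos) <- alt
        subs[[length(subs) + 1L]] <- tibble(
          offset = pos - 1, ref_base = ref, alt_base = alt
        )
      }
      n_subs <- length(subs)
      if (n_subs > max_subs) next
      # core must be gone at every offset overlapping the original core
      if (core_survives(mut, core, core_start, core_end)) next
      cand[[length(cand) + 1L]] <- list(
        enzyme = names(enzymes)[e], site = site, placement = p,
        n_subs = n_subs, mut = mut,
        substitutions = if (n_subs) dplyr::bind_rows(subs) else
          tibble(offset = double(), ref_base = character(), alt_base = character()),
        catalog_order = e
      )
    }
  }

  target <- tibble(start = win_start, end = win_end,
                   core_start = core_start, core_end = core_end, core = core)
  if (!length(cand)) {
    return(structure(
      list(
        feasible = FALSE, accepted = FALSE, target = target,
        substitutions = NULL, mutated_sequence = NULL,
        enzyme = NA_character_, enzyme_site = NA_character_,
        placement = NA_integer_, n_subs = NA_integer_,
        lost_core = FALSE, gained_hits = NULL, lost_hits = NULL
      ),
      class = "mutagenesis_plan"
    ))
  }
  o <- order(
    vapply(cand, `[[`, integer(1), "n_subs"),
    vapply(cand, `[[`, numeric(1), "placement"),
    vapply(cand, `[[`, integer(1), "catalog_order")
  )
  best <- cand[[o[1]]]
  gained <- lost <- NULL
  if (!is.null(pwms)) {
    gl <- verify_no_gain(seq, best$mut, pwms, alpha = alpha)
    gained <- gl$gained
    lost <- gl$lost
  }
  structure(
    list(
      feasible = TRUE,
      accepted = is.null(gained) || nrow(gained) == 0L,
      target = target,
      substitutions = best$substitutions,
      mutated_sequence = best$mut,
      enzyme = best$enzyme, enzyme_site = best$site,
      placement = best$placement, n_subs = best$n_subs,
      lost_core = TRUE,
      gained_hits = gained, lost_hits = lost
    ),
    class = "mutagenesis_plan"
  )
}

core_survives <- function(seq, core, core_start, core_end) {
  k <- nchar(core)
  q_lo <- max(0L, core_start - k + 1L)
  q_hi <- min(nchar(seq) - k, core_end - 1L)
  if (q_lo > q_hi) return(FALSE)
  any(vapply(q_lo:q_hi, function(q) {
    matches_core(substr(seq, q + 1, q + k), core)
  }, logical(1)))
}

#' @export
print.mutagenesis_plan <- function(x, ...) {
  if (!x$feasible) {
    cat("<mutagenesis_plan> infeasible: no placement destroys the core within max_subs\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<mutagenesis_plan> %s site at %d: %d substitution(s), core lost, %s\n",
    x$enzyme, x$placement, x$n_subs,
    if (is.null(x$gained_hits)) "re-scan not run" else
      sprintf("%d gained / %d lost hit(s)", nrow(x$gained_hits), nrow(x$lost_hits))
  ))
  invisible(x)
}

#' Re-scan a mutated sequence for gained and lost binding sites
#'
#' Scans wild-type and mutant with the same PWM set at the same cutoff and
#' reports hits present in the mutant but not at the same
#' interval+strand+PWM in the wild type (`gained`), and the converse
#' (`lost`).
#'
#' @param wt_seq,mut_seq Equal-length sequence strings.
#' @param pwms List of `pwm` objects.
#' @param alpha Per-window p-value cutoff.
#' @param granularity Score rounding step in bits.
#' @return A list with hit tibbles `gained` and `lost`.
#' @export
verify_no_gain <- function(wt_seq, mut_seq, pwms, alpha = 0.01, granularity = 0.01) {
  if (nchar(wt_seq) != nchar(mut_seq)) {
    abort("wild-type and mutant sequences differ in length")
  }
  key <- c("pwm", "start", "end", "strand")
  wt <- scan_sequence_set(wt_seq, pwms, alpha = alpha, granularity = granularity)
  mut <- scan_sequence_set(mut_seq, pwms, alpha = alpha, granularity = granularity)
  list(
    gained = dplyr::anti_join(mut, wt, by = key),
    lost = dplyr::anti_join(wt, mut, by = key)
  )
}

#' Edge-to-edge distances between binding-site hits
#'
#' Reports, for every pair of hits, the number of bases between their
#' nearest edges; overlapping or adjacent hits get 0.
#'
#' @param hits Hit tibble (>= 2 rows) on one sequence.
#' @return Tibble with `pwm_i`, `pwm_j`, `start_i`, `start_j`,
#'   `distance_bp`.
#' @export
pairwise_site_distance <- function(hits) {
  if (nrow(hits) < 2L) abort("need at least two hits")
  pairs <- utils::combn(nrow(hits), 2L)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]
    j <- pairs[2, k]
    tibble(
      pwm_i = hits$pwm[i], pwm_j = hits$pwm[j],
      start_i = hits$start[i], start_j = hits$start[j],
      distance_bp = max(
        0,
        max(hits$start[i], hits$start[j]) - min(hits$end[i], hits$end[j])
      )
    )
  })
}
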