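# Full locus screen: conservation -> length/exon/blacklist filters -> TFBS
# presence -> chromatin-mark scoring with repressive veto -> signed labels
# -> TAD/accessibility annotation, with a per-stage count log.

#' Screen a locus for candidate cis-regulatory modules
#'
#' Runs the whole evidence cascade on one locus. `config` is a named list:
#'
#' * `alignment` — aligned FASTA (reference first, other species second)
#' * `gff3` — gene annotation; `exon`/`CDS` features are excluded regions
#' * `blacklist` — BED of previously described elements to exclude
#' * `marks` — named list of peak BED paths, one per chromatin mark
#' * `pwms` — JASPAR PFM file for the binding-site requirement
#' * `promoter_start`, `promoter_end`, `gene_strand` — promoter interval
#'   (0-based half-open) and the gene's strand
#' * optional `contact_matrix` + `contact_bins`, `ctcf`, `atac` — when
#'   present, candidates are annotated with a same-TAD flag (vs the
#'   promoter) and an accessibility flag; when absent those columns are
#'   `NA` with a warning (annotations, not filters, unless
#'   `require_same_tad`/`require_accessible` is set)
#' * tunables with defaults: `window_bp` 100, `min_identity` 0.7,
#'   `min_len` 150, `max_len` 2100, `min_marks` 3, `alpha` 1e-2
#'
#' Candidate regions that carry at least `min_marks` distinct active marks,
#' no repressive mark and at least one binding-site hit are labelled by
#' promoter side (negative = upstream) and distance rank.
#'
#' @param config Named list as above.
#' @return An object of class `screen_report`: `candidates` (labelled
#'   tibble), `conserved` (all conserved regions pre-classification),
#'   `log` (per-stage counts), `tads` (a `tad_set` or `NULL`), `config`.
#' @export
screen_locus <- function(config) {
  defaults <- list(
    window_bp = 100L, min_identity = 0.7, min_len = 150, max_len = 2100,
    min_marks = 3L, alpha = 0.01,
    require_same_tad = FALSE, require_accessible = FALSE
  )
  config <- utils::modifyList(defaults, config)
  required <- c("alignment", "gff3", "blacklist", "pwms")
  miss <- setdiff(required, names(config))
  if (length(miss)) abort(sprintf("config lacks required input '%s'", miss[1]))
  if (!length(config$marks)) abort("config lacks mark peak tracks")
  for (p in c(config[required], config$marks,
              config[intersect(c("contact_matrix", "contact_bins", "ctcf", "atac"),
                               names(config))])) {
    if (!file.exists(p)) abort(sprintf("input file missing: %s", p))
  }
  for (f in c("promoter_start", "promoter_end", "gene_strand")) {
    if (is.null(config[[f]])) abort(sprintf("config lacks '%s'", f))
  }

  log <- list()
  note <- function(stage, n_in, n_out) {
    log[[length(log) + 1L]] <<- tibble(stage = stage, n_in = n_in, n_out = n_out)
  }

  aln <- parse_fasta(config$alignment, aligned = TRUE)
  if (nrow(aln) < 2L) abort("alignment needs at least two records")
  chrom <- aln$id[1]
  profile <- window_identity(aln$seq[1], aln$seq[2], config$window_bp)
  regions <- call_conserved_regions(profile, config$min_identity,
                                    config$window_bp, chrom = chrom)
  note("conservation", nrow(profile), nrow(regions))

  ann <- parse_intervals(config$gff3, "gff3")
  exons <- ann[ann$type %in% c("exon", "CDS", "five_prime_UTR", "three_prime_UTR"), ]
  exons$chrom <- chrom # annotation is in reference coordinates
  blacklist <- parse_intervals(config$blacklist, "bed")
  if (nrow(blacklist)) blacklist$chrom <- chrom
  filtered <- filter_candidates(regions, exons, blacklist,
                                config$min_len, config$max_len)
  note("length/exon/blacklist filter", nrow(regions), nrow(filtered))

  pwms <- read_jaspar_pfm(config$pwms)
  ref_seq <- gsub("-", "", aln$seq[1], fixed = TRUE)
  filtered$n_tfbs <- vapply(seq_len(nrow(filtered)), function(i) {
    sub <- substr(ref_seq, filtered$start[i] + 1, filtered$end[i])
    nrow(scan_sequence_set(sub, pwms, alpha = config$alpha))
  }, integer(1))
  filtered$has_tfbs <- filtered$n_tfbs > 0L
  note("TFBS presence", nrow(filtered), sum(filtered$has_tfbs))

  tracks <- lapply(config$marks, function(p) {
    x <- parse_intervals(p, "bed")
    if (nrow(x)) x$chrom <- chrom
    x
  })
  profiled <- count_marks(filtered, tracks)
  keep <- classify_pcrm(profiled, config$min_marks)
  candidates <- profiled[keep, , drop = FALSE]
  note("mark scoring + repressive veto", nrow(profiled), nrow(candidates))

  promoter <- genomic_intervals(chrom, config$promoter_start,
                                config$promoter_end, name = "promoter")
  candidates <- label_pcrms(candidates, promoter, config$gene_strand)
  note("promoter-side labelling", nrow(candidates), nrow(candidates))

  tads <- NULL
  if (!is.null(config$contact_matrix)) {
    cm <- parse_contact_matrix(config$contact_matrix, config$contact_bins)
    tads <- call_tads(insulation_profile(cm))
    candidates$same_tad <- vapply(seq_len(nrow(candidates)), function(i) {
      same_tad(candidates[i, ], promoter, tads)
    }, logical(1))
  } else {
    warn("no contact matrix supplied; same_tad column is NA")
    candidates$same_tad <- NA
  }
  if (!is.null(config$atac)) {
    atac <- parse_intervals(config$atac, "bed")
    if (nrow(atac)) atac$chrom <- chrom
    candidates$accessible <- is_accessible(candidates, atac)
  } else {
    warn("no ATAC peaks supplied; accessible column is NA")
    candidates$accessible <- NA
  }
  n_ann <- nrow(candidates)
  if (isTRUE(config$require_same_tad)) {
    candidates <- candidates[!is.na(candidates$same_tad) & candidates$same_tad, ]
  }
  if (isTRUE(config$require_accessible)) {
    candidates <- candidates[!is.na(candidates$accessible) & candidates$accessible, ]
  }
  note("TAD/accessibility annotation", n_ann, nrow(candidates))

  structure(
    list(
      candidates = candidates,
      conserved = profiled,
      log = dplyr::bind_rows(log),
      tads = tads,
      config = config
    ),
    class = "screen_report"
  )
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("<screen_report> %d candidate CRM(s) from %d conserved region(s)\n",
              nrow(x$candidates), x$log$n_in[2]))
  print(x$log)
  print(x$candidates[, intersect(
    c("label", "chrom", "start", "end", "length_bp", "identity",
      "n_active_marks", "has_tfbs", "same_tad", "accessible"),
    names(x$candidates)
  )])
  invisible(x)
}

#' Write a screen report as TSV + manifest
#'
#' Emits `report.tsv` (one row per labelled candidate; mark list collapsed
#' to a comma-separated field), `stage_log.tsv`, and `manifest.json` echoing
#' the configuration. Output is deterministic: identical inputs give
#' byte-identical files.
#'
#' @param report A [screen_locus()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_screen_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  x <- report$candidates
  x$marks_present <- vapply(x$marks_present, paste, character(1), collapse = ",")
  readr::write_tsv(x, file.path(dir, "report.tsv"))
  readr::write_tsv(report$log, file.path(dir, "stage_log.tsv"))
  cfg <- report$config
  cfg$marks <- as.list(cfg$marks)
  jsonlite::write_json(
    list(config = cfg, n_candidates = nrow(report$candidates)),
    file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
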