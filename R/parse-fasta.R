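#' Read (aligned) FASTA sequences
#'
#' Sequences are upper-cased on read and restricted to the `{A,C,G,T,N}`
#' alphabet (plus `-` for aligned input). With `aligned = TRUE` all records
#' must have equal length, as produced by a pairwise or multiple aligner.
#'
#' @param path FASTA file.
#' @param aligned Require equal-length records and permit the gap character.
#' @return A tibble with columns `id` and `seq`.
#' @export
parse_fasta <- function(path, aligned = FALSE) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(sprintf("cannot read FASTA '%s': %s", path, conditionMessage(e)))
  )
  if (length(set) == 0L) abort(sprintf("empty FASTA: %s", path))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate FASTA id: %s", ids[duplicated(ids)][1]))
  }
  seqs <- toupper(as.character(set))
  allowed <- if (aligned) "ACGTN-" else "ACGTN"
  bad <- grepl(sprintf("[^%s]", allowed), seqs)
  if (any(bad)) {
    abort(sprintf("record '%s' contains characters outside {%s}", ids[bad][1], allowed))
  }
  if (any(nchar(seqs) < 1L)) abort("zero-length sequence record")
  if (aligned && length(unique(nchar(seqs))) != 1L) {
    abort("aligned FASTA records have unequal lengths")
  }
  tibble(id = ids, seq = unname(seqs))
}

#' Write sequences as FASTA
#'
#' @param x Tibble with `id` and `seq` columns (as from [parse_fasta()]).
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  out <- unlist(lapply(seq_len(nrow(x)), function(i) {
    body <- substring(
      x$seq[i],
      seq(1, nchar(x$seq[i]), by = width),
      pmin(seq(1, nchar(x$seq[i]), by = width) + width - 1L, nchar(x$seq[i]))
    )
    c(paste0(">", x$id[i]), body)
  }))
  writeLines(out, path)
  invisible(path)
}
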