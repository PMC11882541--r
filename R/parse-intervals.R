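#' Read genomic intervals from BED, GFF3 or bedGraph text
#'
#' All three dialects are returned in the package's single internal
#' convention: 0-based half-open coordinates. GFF3 (1-based closed) is
#' converted at this boundary, so `start` is decremented by one; bedGraph
#' rows carry their signal in a `value` column. Input row order is
#' preserved.
#'
#' @param path Path to a text file in the named dialect.
#' @param format One of `"bed"`, `"gff3"`, `"bedgraph"`.
#' @return A tibble of intervals (`chrom`, `start`, `end`, `strand`, `name`),
#'   plus `score` for BED files with 5+ columns, `value` for bedGraph, and
#'   `type`/`attributes` for GFF3.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr2\t100\t200\tpeak1", bed)
#' parse_intervals(bed, "bed")
#' @export
parse_intervals <- function(path, format = c("bed", "gff3", "bedgraph")) {
  format <- match.arg(tolower(format[1]), c("bed", "gff3", "bedgraph"))
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  keep <- !grepl("^\\s*$", lines) &
    !startsWith(lines, "#") &
    !startsWith(lines, "track") &
    !startsWith(lines, "browser")
  idx <- which(keep)
  if (!length(idx)) {
    return(genomic_intervals(character(), double(), double())[0, ])
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)

  need <- switch(format, bed = 3L, bedgraph = 4L, gff3 = 9L)
  nf <- lengths(fields)
  bad <- which(nf < need)
  if (length(bad)) {
    abort(sprintf(
      "%s line %d: expected >= %d tab-separated fields, got %d",
      format, idx[bad[1]], need, nf[bad[1]]
    ))
  }

  col <- function(k) vapply(fields, function(f) if (length(f) >= k) f[k] else NA_character_, character(1))
  num <- function(v, k) {
    out <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(out) & !is.na(v))
    if (length(bad)) {
      abort(sprintf("%s line %d: field %d is not numeric ('%s')", format, idx[bad[1]], k, v[bad[1]]))
    }
    out
  }

  if (format == "gff3") {
    start1 <- num(col(4), 4)
    end1 <- num(col(5), 5)
    out <- tibble(
      chrom = col(1),
      start = start1 - 1,   # 1-based closed -> 0-based half-open
      end = end1,
      strand = ifelse(col(7) %in% c("+", "-"), col(7), "."),
      name = gff3_attr(col(9), "ID"),
      type = col(3),
      attributes = col(9)
    )
  } else {
    out <- tibble(
      chrom = col(1),
      start = num(col(2), 2),
      end = num(col(3), 3),
      strand = ".",
      name = NA_character_
    )
    if (format == "bed") {
      if (any(nf >= 4)) out$name <- col(4)
      if (any(nf >= 5)) out$score <- suppressWarnings(as.numeric(col(5)))
      if (any(nf >= 6)) {
        s <- col(6)
        out$strand <- ifelse(s %in% c("+", "-"), s, ".")
      }
    } else {
      out$value <- num(col(4), 4)
    }
  }

  inv <- which(!(out$start >= 0 & out$start < out$end))
  if (length(inv)) {
    abort(sprintf(
      "%s line %d: inverted or empty interval (start=%s >= end=%s)",
      format, idx[inv[1]], format(out$start[inv[1]]), format(out$end[inv[1]])
    ))
  }
  validate_intervals(out, format)
  out
}

gff3_attr <- function(attr, key) {
  vapply(regmatches(attr, gregexpr(paste0("(^|;)\\s*", key, "=[^;]*"), attr)),
         function(x) if (length(x) && nzchar(x[1])) sub(paste0(".*", key, "="), "", x[1]) else NA_character_,
         character(1))
}

#' Write intervals as BED
#'
#' Emits BED3/4/5/6 depending on which optional columns are present.
#' Intervals round-trip through [parse_intervals()] unchanged.
#'
#' @param x Interval tibble (see [genomic_intervals()]); an optional `score`
#'   column becomes BED column 5.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  cols <- list(x$chrom, format_coord(x$start), format_coord(x$end))
  has_name <- "name" %in% names(x) && any(!is.na(x$name))
  has_score <- "score" %in% names(x) && any(!is.na(x$score))
  has_strand <- "strand" %in% names(x) && any(x$strand != ".")
  if (has_name || has_score || has_strand) {
    cols <- c(cols, list(ifelse(is.na(x$name), ".", x$name)))
  }
  if (has_score || has_strand) {
    sc <- if ("score" %in% names(x)) x$score else rep(0, nrow(x))
    cols <- c(cols, list(ifelse(is.na(sc), "0", format(sc, trim = TRUE, scientific = FALSE))))
  }
  if (has_strand) cols <- c(cols, list(x$strand))
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

format_coord <- function(x) format(x, trim = TRUE, scientific = FALSE, nsmall = 0)
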