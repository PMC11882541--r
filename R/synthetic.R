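# Seed-deterministic synthetic fixtures with planted ground truth. Each
# generator emulates the statistical structure of one input class of the
# screen — conserved blocks in a pairwise alignment with mark-peak tracks,
# block-structured contact matrices, bimodal marker expression, grouped
# reporter intensities — so every pipeline stage can be scored without any
# external download. A master seed fans out to per-stream sub-seeds so
# regenerating one file does not perturb the others.

sub_seed <- function(seed, k) as.integer((as.numeric(seed) * 97 + k * 7919) %% 2147483629 + 1)

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# The synthetic screening motif: a sharp 8-bp PFM planted in positive blocks.
SYNTH_MOTIF_COUNTS <- local({
  consensus <- c("G", "G", "A", "A", "A", "T", "G", "C")
  m <- matrix(1L, 4, length(consensus), dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(consensus)) m[consensus[j], j] <- 37L
  m
})

#' Generate a synthetic locus with planted conserved blocks
#'
#' Writes an aligned FASTA (reference + one other species), a GFF3 gene
#' annotation, a blacklist BED, one peak BED per chromatin mark, ATAC and
#' CTCF BEDs, a JASPAR-format PFM of the planted screening motif, a
#' companion contact matrix, and a manifest JSON — all deterministic given
#' `seed`. Exactly `n_positive` blocks receive >= 3 distinct active marks
#' and no repressive mark (and carry the motif consensus); the remaining
#' blocks get 0–2 active marks or an active set vetoed by a repressive
#' peak, so the planted screen outcome is known exactly.
#'
#' @param dir Output directory (created if needed).
#' @param seed Master seed.
#' @param n_blocks Number of conserved blocks (default 49, the fixture's
#'   locus-scan convention).
#' @param n_positive Blocks planted to pass the screen (default 12, split
#'   `n_upstream_positive` upstream / rest downstream of the promoter).
#' @param n_upstream_positive Positives upstream of the promoter (default 10).
#' @param block_len_range,spacer_len_range Uniform sampling ranges in bp.
#'   Block lengths default to `[300, 2000]`: at the window size used for
#'   identity profiling, edge erosion makes blocks near the 150 bp filter
#'   floor unrecoverable, so planted blocks stay clear of it.
#' @param block_identity,spacer_identity Per-base identity of the second
#'   species inside/outside blocks (defaults 0.9 and 0.45).
#' @param n_veto Negative blocks given >= 3 active marks plus a repressive
#'   peak (exercises the veto; default 4).
#' @param bin_bp Contact-matrix bin width (default 1000).
#' @return Invisibly, a list with `truth` (planted blocks tibble with
#'   `positive`, `marks`, promoter, boundary bins, seed) and `paths`
#'   (named file paths). Also written as `manifest.json` in `dir`.
#' @export
synth_locus <- function(dir, seed = 1L, n_blocks = 49L, n_positive = 12L,
                        n_upstream_positive = 10L,
                        block_len_range = c(300L, 2000L),
                        spacer_len_range = c(300L, 800L),
                        block_identity = 0.9, spacer_identity = 0.45,
                        n_veto = 4L, bin_bp = 1000L) {
  if (n_positive > n_blocks) abort("n_positive exceeds n_blocks")
  if (n_upstream_positive > n_positive) abort("n_upstream_positive exceeds n_positive")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  chrom <- "synthetic_locus"

  # --- layout ------------------------------------------------------------
  set.seed(sub_seed(seed, 1))
  blens <- sample(block_len_range[1]:block_len_range[2], n_blocks, replace = TRUE)
  slens <- sample(spacer_len_range[1]:spacer_len_range[2], n_blocks + 1L, replace = TRUE)
  # promoter sits in the spacer after this block: upstream blocks before it
  promoter_after <- n_blocks - max(3L, ceiling((n_blocks - n_upstream_positive) / 6L)) - 2L
  promoter_after <- max(n_upstream_positive, min(n_blocks - (n_positive - n_upstream_positive), promoter_after))
  # widen that spacer so promoter (1 kb) and the exons fit clear of blocks
  slens[promoter_after + 1L] <- max(slens[promoter_after + 1L], 3200L)

  starts <- ends <- numeric(n_blocks)
  pos <- slens[1]
  for (i in seq_len(n_blocks)) {
    starts[i] <- pos
    ends[i] <- pos + blens[i]
    pos <- ends[i] + slens[i + 1L]
  }
  locus_len <- pos
  if (locus_len > 5e6) abort("blocks cannot fit in a reasonable locus length")
  promoter_start <- ends[promoter_after] + round(slens[promoter_after + 1L] / 2) - 500
  promoter <- genomic_intervals(chrom, promoter_start, promoter_start + 1000,
                                strand = "+", name = "promoter")

  upstream_idx <- seq_len(promoter_after)
  downstream_idx <- setdiff(seq_len(n_blocks), upstream_idx)
  positives <- sort(c(
    sample(upstream_idx, n_upstream_positive),
    sample(downstream_idx, n_positive - n_upstream_positive)
  ))
  negatives <- setdiff(seq_len(n_blocks), positives)
  veto_idx <- if (length(negatives)) sample(negatives, min(n_veto, length(negatives))) else integer()

  # --- sequences ---------------------------------------------------------
  set.seed(sub_seed(seed, 2))
  ref <- random_dna(locus_len)
  motif <- paste(rownames(SYNTH_MOTIF_COUNTS)[apply(SYNTH_MOTIF_COUNTS, 2, which.max)],
                 collapse = "")
  for (i in positives) {
    at <- floor((starts[i] + ends[i]) / 2) - floor(nchar(motif) / 2)
    substr(ref, at + 1, at + nchar(motif)) <- motif
  }
  keep <- rep(spacer_identity, locus_len)
  for (i in seq_len(n_blocks)) keep[(starts[i] + 1):ends[i]] <- block_identity
  ch <- strsplit(ref, "", fixed = TRUE)[[1]]
  flip <- runif(locus_len) > keep
  ch[flip] <- vapply(ch[flip], function(b) sample(setdiff(BASES, b), 1L), character(1))
  other <- paste(ch, collapse = "")

  # --- annotations -------------------------------------------------------
  set.seed(sub_seed(seed, 3))
  # gene: promoter TSS + two downstream exons placed inside the widened spacer
  gene_end <- min(locus_len, promoter$end[1] + 6000)
  gff <- c(
    "##gff-version 3",
    sprintf("%s\tsynth\tgene\t%d\t%d\t.\t+\t.\tID=gene1",
            chrom, promoter$end[1] - 499, gene_end),
    sprintf("%s\tsynth\texon\t%d\t%d\t.\t+\t.\tID=exon1;Parent=gene1",
            chrom, promoter$end[1] + 1, promoter$end[1] + 180),
    sprintf("%s\tsynth\texon\t%d\t%d\t.\t+\t.\tID=exon2;Parent=gene1",
            chrom, promoter$end[1] + 601, promoter$end[1] + 900)
  )
  # blacklist: two prior-element intervals centred in upstream spacers,
  # >= 100 bp clear of block edges so called-region jitter cannot touch them
  spacer_mid <- function(k) if (k == 1L) slens[1] %/% 2 else ends[k - 1L] + slens[k] %/% 2
  blacklist <- genomic_intervals(
    chrom,
    c(spacer_mid(1L) - 50, spacer_mid(2L) - 50),
    c(spacer_mid(1L) + 50, spacer_mid(2L) + 50),
    name = c("prior_cne_1", "prior_cne_2")
  )

  # --- mark peaks --------------------------------------------------------
  set.seed(sub_seed(seed, 4))
  mark_sets <- vector("list", n_blocks)
  for (i in positives) {
    mark_sets[[i]] <- sample(ACTIVE_MARKS, sample(3:5, 1))
  }
  for (i in negatives) {
    if (i %in% veto_idx) {
      mark_sets[[i]] <- c(sample(ACTIVE_MARKS, sample(3:5, 1)), REPRESSIVE_MARKS[1])
    } else {
      k <- sample(0:2, 1)
      mark_sets[[i]] <- if (k) sample(ACTIVE_MARKS, k) else character()
    }
  }
  all_marks <- c(ACTIVE_MARKS, REPRESSIVE_MARKS)
  peak_paths <- setNames(file.path(dir, paste0("peaks_", all_marks, ".bed")), all_marks)
  for (mk in all_marks) {
    has <- which(vapply(mark_sets, function(s) mk %in% s, logical(1)))
    if (length(has)) {
      jit <- sample(10:40, length(has), replace = TRUE)
      peaks <- genomic_intervals(
        chrom,
        starts[has] + jit,
        pmax(starts[has] + jit + 60, ends[has] - jit),
        name = sprintf("%s_peak_%03d", mk, seq_along(has))
      )
    } else {
      peaks <- genomic_intervals(character(), double(), double())[0, ]
    }
    write_bed(peaks, peak_paths[[mk]])
  }

  # ATAC: positives are accessible; CTCF: at the contact-matrix boundary
  atac <- genomic_intervals(chrom, starts[positives] + 5, ends[positives] - 5,
                            name = sprintf("atac_%03d", seq_along(positives)))
  n_bins <- as.integer(ceiling(locus_len / bin_bp)) # bins must cover the locus
  boundary_bin <- n_bins %/% 2
  ctcf <- genomic_intervals(chrom,
    c(boundary_bin * bin_bp - 200),
    c(boundary_bin * bin_bp + 200),
    name = "ctcf_1"
  )

  # --- contact matrix ----------------------------------------------------
  cm <- synth_contact_matrix(
    n_bins = n_bins, bin_bp = bin_bp, boundaries = boundary_bin + 1L,
    intra_mean = 10, inter_mean = 2, noise_cv = 0.2,
    seed = sub_seed(seed, 5), chrom = chrom
  )$cm

  # --- write -------------------------------------------------------------
  paths <- list(
    alignment = file.path(dir, "alignment.fa"),
    gff3 = file.path(dir, "annotation.gff3"),
    blacklist = file.path(dir, "blacklist.bed"),
    atac = file.path(dir, "atac.bed"),
    ctcf = file.path(dir, "ctcf.bed"),
    pwms = file.path(dir, "motifs.pfm"),
    contact_matrix = file.path(dir, "contacts.tsv"),
    contact_bins = file.path(dir, "contact_bins.bed"),
    manifest = file.path(dir, "manifest.json")
  )
  paths$marks <- as.list(peak_paths)
  write_fasta(tibble(id = c("ref", "other"), seq = c(ref, other)), paths$alignment)
  writeLines(gff, paths$gff3)
  write_bed(blacklist, paths$blacklist)
  write_bed(atac, paths$atac)
  write_bed(ctcf, paths$ctcf)
  writeLines(c(
    ">SYN0001.1 SYNMOTIF",
    sprintf("%s [ %s ]", c("A", "C", "G", "T"),
            apply(SYNTH_MOTIF_COUNTS, 1, paste, collapse = " "))
  ), paths$pwms)
  write_contact_matrix(cm, paths$contact_matrix, paths$contact_bins)

  blocks <- tibble(
    chrom = chrom, start = starts, end = ends, strand = ".",
    name = sprintf("block_%03d", seq_len(n_blocks)),
    identity_planned = block_identity,
    positive = seq_len(n_blocks) %in% positives,
    vetoed = seq_len(n_blocks) %in% veto_idx,
    marks = I(mark_sets)
  )
  truth <- list(
    seed = seed, chrom = chrom, locus_len = locus_len,
    blocks = blocks, promoter = promoter, gene_strand = "+",
    positives = positives, boundary_bins = boundary_bin + 1L,
    block_identity = block_identity, spacer_identity = spacer_identity
  )
  jsonlite::write_json(
    list(
      seed = seed, paths = lapply(paths[names(paths) != "marks"], identity),
      mark_paths = as.list(peak_paths),
      blocks = blocks[, setdiff(names(blocks), "marks")],
      positives = positives,
      promoter = promoter
    ),
    paths$manifest, auto_unbox = TRUE, digits = NA
  )
  invisible(list(truth = truth, paths = paths))
}

#' Generate a block-structured synthetic contact matrix
#'
#' Domains are constant blocks of `intra_mean` with `inter_mean` between
#' them, under multiplicative lognormal noise of coefficient of variation
#' `noise_cv` (mean 1); the matrix is symmetric by construction and
#' deterministic given `seed`.
#'
#' @param n_bins,bin_bp Matrix size and bin width.
#' @param boundaries First bin (1-based) of each new domain; empty for a
#'   single domain.
#' @param intra_mean,inter_mean Within/between-domain contact levels
#'   (`inter_mean < intra_mean`).
#' @param noise_cv Noise coefficient of variation (0 = exact block matrix).
#' @param seed RNG seed.
#' @param chrom Bin sequence name.
#' @return List with `cm` (a [contact_matrix()]) and `truth` (boundary bins
#'   and parameters).
#' @export
synth_contact_matrix <- function(n_bins = 200L, bin_bp = 500L,
                                 boundaries = c(81L, 131L),
                                 intra_mean = 10, inter_mean = 2,
                                 noise_cv = 0.3, seed = 1L,
                                 chrom = "synthetic_matrix") {
  if (inter_mean >= intra_mean) abort("inter_mean must be < intra_mean")
  boundaries <- as.integer(sort(boundaries))
  if (length(boundaries) && (min(boundaries) < 2L || max(boundaries) > n_bins)) {
    abort("boundary index outside 2..n_bins")
  }
  domain <- findInterval(seq_len(n_bins), boundaries) + 1L
  base <- ifelse(outer(domain, domain, `==`), intra_mean, inter_mean)
  set.seed(seed)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    noise <- matrix(rlnorm(n_bins^2, meanlog = -sdlog^2 / 2, sdlog = sdlog), n_bins)
    noise[lower.tri(noise)] <- t(noise)[lower.tri(noise)]
    base <- base * noise
  }
  bins <- genomic_intervals(
    chrom,
    (seq_len(n_bins) - 1) * bin_bp,
    seq_len(n_bins) * bin_bp,
    name = sprintf("bin_%04d", seq_len(n_bins))
  )
  list(
    cm = contact_matrix(bins, base),
    truth = list(
      seed = seed, boundaries = boundaries, n_bins = n_bins, bin_bp = bin_bp,
      intra_mean = intra_mean, inter_mean = inter_mean, noise_cv = noise_cv
    )
  )
}

#' Generate a synthetic cells-by-genes expression matrix
#'
#' The marker column is bimodal around the 0.5 classification threshold
#' (on-cells uniform on [0.5, 4), off-cells uniform on [0, 0.5)); each
#' candidate gene is "on" with probability `p1` in marker-positive cells
#' and `p2` in marker-negative cells.
#'
#' @param n_cells Number of cells (>= 10).
#' @param marker_fraction Fraction of marker-positive cells.
#' @param p1,p2 Candidate on-probabilities in marker+/marker- cells.
#' @param n_candidates Number of candidate genes.
#' @param seed RNG seed.
#' @param marker_gene Marker column name.
#' @return List with `mat` (matrix, rows cells) and `truth`.
#' @export
synth_expression <- function(n_cells = 1000L, marker_fraction = 0.5,
                             p1 = 0.6, p2 = 0.1, n_candidates = 3L,
                             seed = 1L, marker_gene = "marker") {
  if (n_cells < 10L) abort("n_cells must be >= 10")
  stopifnot(p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1)
  set.seed(seed)
  on_value <- function(n) runif(n, 0.5, 4)
  off_value <- function(n) runif(n, 0, 0.5)
  marker_pos <- runif(n_cells) < marker_fraction
  marker <- numeric(n_cells)
  marker[marker_pos] <- on_value(sum(marker_pos))
  marker[!marker_pos] <- off_value(sum(!marker_pos))
  cand <- matrix(0, n_cells, n_candidates)
  for (j in seq_len(n_candidates)) {
    on <- runif(n_cells) < ifelse(marker_pos, p1, p2)
    cand[on, j] <- on_value(sum(on))
    cand[!on, j] <- off_value(sum(!on))
  }
  mat <- cbind(marker, cand)
  colnames(mat) <- c(marker_gene, sprintf("candidate_%d", seq_len(n_candidates)))
  rownames(mat) <- sprintf("cell_%04d", seq_len(n_cells))
  list(
    mat = mat,
    truth = list(
      seed = seed, marker_positive = marker_pos, p1 = p1, p2 = p2,
      marker_fraction = marker_fraction
    )
  )
}

#' Generate synthetic grouped reporter-fluorescence records
#'
#' Normalized intensities are normal with control mean 1.0 and group mean
#' `1.0 + effect * control_sd`; RFP is lognormal around `rfp_mean` and
#' GFP is reconstructed as `normalized * RFP`, so normalization recovers
#' the planted values exactly.
#'
#' @param groups Tibble with columns `group`, `n` (>= 2), `effect`
#'   (in units of `control_sd`; use 0 for the control).
#' @param control_sd Within-group standard deviation (> 0).
#' @param rfp_mean Typical RFP intensity.
#' @param seed RNG seed.
#' @return List with `records` (tibble: `embryo_id`, `group`, `gfp_mean`,
#'   `rfp_mean`) and `truth`.
#' @export
synth_fluorescence <- function(groups, control_sd = 0.15, rfp_mean = 100,
                               seed = 1L) {
  if (control_sd <= 0) abort("control_sd must be > 0")
  if (any(groups$n < 2L)) abort("every group needs n >= 2")
  set.seed(seed)
  records <- purrr::pmap_dfr(groups, function(group, n, effect) {
    normalized <- rnorm(n, mean = 1 + effect * control_sd, sd = control_sd)
    normalized <- pmax(normalized, 0)
    rfp <- rlnorm(n, meanlog = log(rfp_mean), sdlog = 0.2)
    tibble(
      embryo_id = sprintf("%s_e%02d", group, seq_len(n)),
      group = group,
      gfp_mean = normalized * rfp,
      rfp_mean = rfp
    )
  })
  list(records = records, truth = list(seed = seed, groups = groups,
                                       control_sd = control_sd))
}
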