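# Shared fixtures and independent oracles, built in code at test time.

# Independent brute-force oracle for the PWM score distribution: enumerate
# all 4^L words, score each as the sum of per-column rounded units, weight
# by the background. Shares nothing with the package's convolution code.
brute_force_tail <- function(pwm, granularity, at_units) {
  L <- pwm$length
  units <- round(pwm$log_odds / granularity)
  words <- as.matrix(expand.grid(rep(list(1:4), L)))
  scores <- vapply(seq_len(nrow(words)), function(r) {
    sum(units[cbind(words[r, ], seq_len(L))])
  }, double(1))
  weights <- vapply(seq_len(nrow(words)), function(r) {
    prod(pwm$background[words[r, ]])
  }, double(1))
  lev <- sort(unique(scores))
  mass <- vapply(split(weights, factor(scores, levels = lev)), sum, double(1))
  tail_at_lev <- rev(cumsum(rev(mass)))
  vapply(at_units, function(u) {
    i <- findInterval(u - 0.5, lev) + 1L # first level >= u
    if (i > length(lev)) 0 else unname(tail_at_lev[i])
  }, double(1))
}

random_pwm <- function(L, name = "rand") {
  counts <- matrix(sample(0:25, 4 * L, replace = TRUE), nrow = 4)
  counts[, colSums(counts) == 0] <- 1 # avoid all-zero columns
  pwm_from_counts(counts, name = name)
}

random_dna_string <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# A small, sharp test PWM whose consensus is GGAA-like (Ets flavour).
ets_like_pwm <- function() {
  counts <- rbind(
    A = c(0, 0, 24, 24, 4, 0),
    C = c(0, 0, 0, 0, 4, 24),
    G = c(24, 24, 0, 0, 8, 0),
    T = c(0, 0, 0, 0, 8, 0)
  )
  pwm_from_counts(counts, name = "ets_like")
}

# Deterministic enzyme catalog for mutagenesis tests.
enzyme_catalog <- function() {
  c(
    EcoRI = "GAATTC", BamHI = "GGATCC", HindIII = "AAGCTT",
    XhoI = "CTCGAG", NheI = "GCTAGC", SpeI = "ACTAGT"
  )
}

# Screen configuration wired to a synth_locus() result.
locus_config <- function(sl, ...) {
  utils::modifyList(list(
    alignment = sl$paths$alignment, gff3 = sl$paths$gff3,
    blacklist = sl$paths$blacklist, marks = sl$paths$marks,
    pwms = sl$paths$pwms,
    contact_matrix = sl$paths$contact_matrix,
    contact_bins = sl$paths$contact_bins,
    ctcf = sl$paths$ctcf, atac = sl$paths$atac,
    promoter_start = sl$truth$promoter$start,
    promoter_end = sl$truth$promoter$end,
    gene_strand = sl$truth$gene_strand
  ), list(...))
}

# Independent re-derivation of the expected signed labels from planted truth
# (midpoint side + distance rank), sharing no code with label_pcrms().
expected_labels <- function(truth) {
  blocks <- truth$blocks[truth$blocks$positive, ]
  pm <- (truth$promoter$start + truth$promoter$end) / 2
  mid <- (blocks$start + blocks$end) / 2
  up <- mid < pm
  lab <- integer(nrow(blocks))
  lab[up] <- -rank(abs(mid[up] - pm), ties.method = "first")
  lab[!up] <- rank(abs(mid[!up] - pm), ties.method = "first")
  blocks$label_expected <- lab
  blocks
}
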