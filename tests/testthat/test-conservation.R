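test_that("windowed identity matches hand-computed values", {
  # full-length window: 3 of 4 bases match at every position
  p <- window_identity("AAAA", "AAAT", window_bp = 4)
  expect_equal(p$identity, rep(0.75, 4))
  expect_equal(p$ref_pos, 0:3)
  # identical sequences are 1.0 everywhere
  s <- strrep("ACGT", 50)
  expect_equal(window_identity(s, s, 100)$identity, rep(1, 200))
  # a gap in the other species counts as a mismatch
  expect_equal(window_identity("AAAAA", "AA-AA", 5)$identity, rep(0.8, 5))
  # N counts as a mismatch too
  expect_equal(window_identity("AAAAA", "AANAA", 5)$identity, rep(0.8, 5))
})

test_that("windowed identity rejects bad input", {
  expect_error(window_identity("AAAA", "AAA", 2), "unequal")
  expect_error(window_identity("AAAA", "AAAT", 5), "exceeds")
  # gaps in the reference do not count as reference positions
  p <- window_identity("AA-AA", "AAAAA", 4)
  expect_equal(nrow(p), 4)
})

test_that("conserved-region calling thresholds and merges runs", {
  prof <- tibble::tibble(ref_pos = 0:499, identity = rep(1, 500))
  r <- call_conserved_regions(prof, 0.7, 100)
  expect_equal(nrow(r), 1)
  expect_equal(c(r$start, r$end), c(0, 500))

  low <- tibble::tibble(ref_pos = 0:499, identity = rep(0.5, 500))
  expect_equal(nrow(call_conserved_regions(low, 0.7, 100)), 0)

  # two runs separated by 10 sub-threshold bases merge at window 100
  id <- c(rep(0.9, 200), rep(0.5, 10), rep(0.9, 200))
  prof2 <- tibble::tibble(ref_pos = seq_along(id) - 1, identity = id)
  r2 <- call_conserved_regions(prof2, 0.7, 100)
  expect_equal(nrow(r2), 1)
  expect_equal(c(r2$start, r2$end), c(0, 410))
  # but remain separate when the gap reaches window/2
  id3 <- c(rep(0.9, 200), rep(0.5, 50), rep(0.9, 200))
  prof3 <- tibble::tibble(ref_pos = seq_along(id3) - 1, identity = id3)
  expect_equal(nrow(call_conserved_regions(prof3, 0.7, 100)), 2)

  expect_error(call_conserved_regions(prof[0, ], 0.7, 100), "empty")
})

test_that("candidate filter applies closed length bounds and exclusions", {
  mk <- function(len) tibble::tibble(
    chrom = "c", start = 1000, end = 1000 + len, strand = ".",
    name = "r", identity = 0.9, length_bp = len
  )
  expect_equal(nrow(filter_candidates(mk(149))), 0)
  expect_equal(nrow(filter_candidates(mk(150))), 1)
  expect_equal(nrow(filter_candidates(mk(2100))), 1)
  expect_equal(nrow(filter_candidates(mk(2101))), 0)

  region <- mk(300)
  bl <- genomic_intervals("c", 1299, 1400) # 1 bp overlap
  expect_equal(nrow(filter_candidates(region, blacklist = bl)), 0)
  bl2 <- genomic_intervals("c", 1300, 1400) # adjacent, no overlap
  expect_equal(nrow(filter_candidates(region, blacklist = bl2)), 1)
  ex <- genomic_intervals("c", 900, 1001) # 1 bp into the region
  expect_equal(nrow(filter_candidates(region, exons = ex)), 0)
})

test_that("planted blocks are recovered within half a window per edge", {
  set.seed(42)
  for (rep in 1:3) {
    blocks <- list(c(400, 1000), c(1400, 2200), c(2700, 3000))
    n <- 3500
    keep <- rep(0.45, n)
    for (b in blocks) keep[(b[1] + 1):b[2]] <- 1
    ref <- random_dna_string(n)
    ch <- strsplit(ref, "")[[1]]
    flip <- runif(n) > keep
    ch[flip] <- vapply(ch[flip], function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
    other <- paste(ch, collapse = "")
    prof <- window_identity(ref, other, 100)
    called <- call_conserved_regions(prof, 0.7, 100)
    expect_equal(nrow(called), length(blocks))
    for (k in seq_along(blocks)) {
      expect_lt(abs(called$start[k] - blocks[[k]][1]), 50)
      expect_lt(abs(called$end[k] - blocks[[k]][2]), 50)
    }
    # output is disjoint and sorted
    expect_true(all(diff(called$start) > 0))
    expect_true(all(called$start[-1] >= called$end[-nrow(called)]))
  }
})

test_that("raising the identity threshold never increases called bases", {
  set.seed(7)
  for (rep in 1:5) {
    id <- pmin(1, pmax(0, stats::runif(600, 0.3, 1)))
    prof <- tibble::tibble(ref_pos = seq_along(id) - 1, identity = id)
    total <- vapply(c(0.5, 0.6, 0.7, 0.8, 0.9), function(th) {
      sum(call_conserved_regions(prof, th, 50)$length_bp)
    }, double(1))
    expect_true(all(diff(total) <= 0))
  }
})

test_that("conserved-region BED export scales identity to the score column", {
  r <- tibble::tibble(
    chrom = "c", start = 0, end = 200, strand = ".", name = "r1",
    identity = 0.856, length_bp = 200
  )
  path <- tempfile(fileext = ".bed")
  write_conserved_bed(r, path)
  back <- parse_intervals(path, "bed")
  expect_equal(back$score, 856)
})
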