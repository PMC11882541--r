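block_cm <- function(n_bins = 40, bin_bp = 1000, boundaries = 21,
                     intra = 10, inter = 0, noise_cv = 0, seed = 1) {
  synth_contact_matrix(
    n_bins = n_bins, bin_bp = bin_bp, boundaries = boundaries,
    intra_mean = intra, inter_mean = max(inter, 1e-9), noise_cv = noise_cv,
    seed = seed
  )$cm
}

test_that("insulation scores are cross-window means", {
  # constant matrix: score equals the constant wherever defined
  bins <- genomic_intervals("m", (0:5) * 1000, (1:6) * 1000)
  cm <- contact_matrix(bins, matrix(3, 6, 6))
  ins <- insulation_profile(cm, min_depth_bp = 2000, max_depth_bp = 2000, n_scales = 1)
  sc <- ins$profile$score
  expect_equal(sc[3:4], c(3, 3))
  expect_true(all(is.na(sc[c(1, 2, 5, 6)])))

  # hand-filled 6x6, w = 2 at bin 3: mean of M[1:2, 4:5]
  M <- matrix(0, 6, 6)
  M[1, 4] <- 8; M[1, 5] <- 2; M[2, 4] <- 4; M[2, 5] <- 6
  M <- M + t(M) + diag(10, 6)
  cm2 <- contact_matrix(bins, M)
  ins2 <- insulation_profile(cm2, 2000, 2000, 1)
  expect_equal(ins2$profile$score[3], mean(c(8, 2, 4, 6)))

  # two zero-linked blocks: the junction bin scores 0
  cmb <- block_cm(n_bins = 10, boundaries = 6)
  insb <- insulation_profile(cmb, 2000, 2000, 1)
  expect_lt(insb$profile$score[5], 1e-6)

  expect_error(insulation_profile(cmb, min_depth_bp = 500), "bin width")
  expect_error(insulation_profile(cmb, 2000, 1000), "max_depth_bp")
})

test_that("TAD calling finds planted boundaries and nothing else", {
  cm <- block_cm(n_bins = 60, boundaries = 31, inter = 1)
  tads <- call_tads(insulation_profile(cm, 3000, 10000, 3))
  expect_equal(length(tads$boundaries), 1)
  expect_lte(abs(tads$boundaries - 31), 1)
  expect_equal(nrow(tads$domains), 2)
  # domains tile the span without overlap
  expect_equal(tads$domains$start[-1], tads$domains$end[-2])
  expect_equal(tads$domains$start[1], 0)
  expect_equal(tads$domains$end[2], 60 * 1000)

  # constant matrix: no boundaries, one spanning domain
  bins <- genomic_intervals("m", (0:39) * 1000, (1:40) * 1000)
  flat <- call_tads(insulation_profile(contact_matrix(bins, matrix(2, 40, 40)),
                                       3000, 8000, 2))
  expect_equal(length(flat$boundaries), 0)
  expect_equal(nrow(flat$domains), 1)

  # delta above the whole normalized range suppresses every boundary
  none <- call_tads(insulation_profile(cm, 3000, 10000, 3), delta = 1.5)
  expect_equal(length(none$boundaries), 0)
})

test_that("boundary count is monotone in delta and threshold", {
  g <- synth_contact_matrix(n_bins = 120, bin_bp = 1000, boundaries = c(41, 81),
                            intra_mean = 10, inter_mean = 2, noise_cv = 0.3,
                            seed = 11)
  ins <- insulation_profile(g$cm, 3000, 15000, 3)
  n_by_delta <- vapply(c(0.005, 0.05, 0.2, 0.6, 1.2), function(d) {
    length(call_tads(ins, delta = d)$boundaries)
  }, 1)
  expect_true(all(diff(n_by_delta) <= 0))
  n_by_thr <- vapply(c(1e-6, 1e-3, 0.05, 0.2), function(th) {
    length(call_tads(ins, threshold = th)$boundaries)
  }, 1)
  expect_true(all(diff(n_by_thr) >= 0))
})

test_that("CTCF concordance is the fraction of matched boundaries", {
  cm <- block_cm(n_bins = 60, boundaries = c(21, 41), inter = 1)
  tads <- call_tads(insulation_profile(cm, 3000, 10000, 3))
  expect_equal(length(tads$boundaries), 2)
  mids <- (tads$bins$start[tads$boundaries] + tads$bins$end[tads$boundaries]) / 2
  both <- genomic_intervals("m", mids - 100, mids + 100)
  expect_equal(boundary_ctcf_concordance(tads, both, tol_bp = 2000), 1)
  one <- both[1, ]
  expect_equal(boundary_ctcf_concordance(tads, one, tol_bp = 2000), 0.5)
  none <- genomic_intervals("m", 0, 200)
  expect_equal(boundary_ctcf_concordance(tads, none, tol_bp = 2000), 0)
  empty <- call_tads(insulation_profile(block_cm(n_bins = 20, boundaries = 11,
                                                 intra = 5, inter = 4.9),
                                        3000, 5000, 2), delta = 1.5)
  expect_true(is.na(boundary_ctcf_concordance(empty, both, 2000)))
})

test_that("same-TAD queries use midpoints with downstream tie convention", {
  cm <- block_cm(n_bins = 60, boundaries = 31, inter = 1)
  tads <- call_tads(insulation_profile(cm, 3000, 10000, 3))
  b_bp <- tads$boundary_bp[1]
  a <- genomic_intervals("m", 1000, 3000)
  b <- genomic_intervals("m", 10000, 12000)
  c2 <- genomic_intervals("m", b_bp + 5000, b_bp + 7000)
  expect_true(same_tad(a, b, tads))
  expect_false(same_tad(a, c2, tads))
  # symmetry + reflexivity
  expect_equal(same_tad(a, b, tads), same_tad(b, a, tads))
  expect_true(same_tad(a, a, tads))
  # midpoint exactly on the boundary belongs to the downstream domain
  on_b <- genomic_intervals("m", b_bp - 500, b_bp + 500)
  expect_true(same_tad(on_b, c2, tads))
  expect_false(same_tad(on_b, a, tads))
  outside <- genomic_intervals("m", 70000, 80000)
  expect_error(same_tad(outside, a, tads), "span")
})

test_that("accessibility is overlap with an ATAC peak", {
  r <- genomic_intervals("c", c(100, 500, 900), c(200, 600, 1000))
  atac <- genomic_intervals("c", c(120, 599), c(180, 650))
  expect_equal(is_accessible(r, atac), c(TRUE, TRUE, FALSE))
  expect_equal(is_accessible(r, atac, min_overlap_bp = 5), c(TRUE, FALSE, FALSE))
  expect_equal(is_accessible(r, atac[0, ]), c(FALSE, FALSE, FALSE))
})

test_that("TAD BED export round-trips boundaries and domains", {
  cm <- block_cm(n_bins = 60, boundaries = 31, inter = 1)
  tads <- call_tads(insulation_profile(cm, 3000, 10000, 3))
  bp <- tempfile(fileext = ".bed")
  dp <- tempfile(fileext = ".bed")
  write_tads_bed(tads, bp, dp)
  doms <- parse_intervals(dp, "bed")
  expect_equal(nrow(doms), nrow(tads$domains))
  expect_equal(doms$start, tads$domains$start)
})
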