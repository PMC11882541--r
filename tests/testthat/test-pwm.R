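test_that("log-odds construction matches the defining formula", {
  # uniform column at vanishing pseudocount: log-odds all ~0
  p0 <- pwm_from_counts(matrix(c(1, 1, 1, 1), 4), pseudocount = 1e-9)
  expect_equal(as.numeric(p0$log_odds), rep(0, 4), tolerance = 1e-6)
  # single-base column, uniform background, pseudocount 1
  p1 <- pwm_from_counts(matrix(c(4, 0, 0, 0), 4), pseudocount = 1)
  expect_equal(unname(p1$log_odds[1, 1]), log2(((4 + 0.25) / 5) / 0.25))
  expect_equal(unname(p1$log_odds[2, 1]), log2(((0 + 0.25) / 5) / 0.25))

  expect_error(pwm_from_counts(matrix(0, 4, 0)), "4 x L")
  expect_error(pwm_from_counts(matrix(c(0, 0, 0, 0, 1, 1, 1, 1), 4)), "all-zero")
  expect_error(pwm_from_counts(matrix(1, 4, 1), background = c(0, 0.5, 0.25, 0.25)),
               "positive")
})

test_that("exact score distribution equals brute-force enumeration", {
  set.seed(101)
  for (L in c(2, 4, 6)) {
    pwm <- random_pwm(L)
    d <- pwm_score_distribution(pwm, 0.01)
    expect_equal(d$tail, brute_force_tail(pwm, 0.01, d$units), tolerance = 1e-12)
    expect_equal(sum(d$prob), 1, tolerance = 1e-12)
  }
  # non-uniform background too
  pwm <- pwm_from_counts(matrix(sample(0:9, 16, TRUE) + 1, 4),
                         background = c(0.4, 0.1, 0.1, 0.4))
  d <- pwm_score_distribution(pwm, 0.01)
  expect_equal(d$tail, brute_force_tail(pwm, 0.01, d$units), tolerance = 1e-12)
})

test_that("p-value thresholding selects the stated tail mass", {
  # one column with a unique best letter: alpha 0.25 keeps exactly it
  pwm <- pwm_from_counts(matrix(c(10, 2, 2, 2), 4))
  th <- exact_pvalue_threshold(pwm, alpha = 0.25)
  expect_equal(th$tail_prob, 0.25)
  expect_equal(th$threshold, max(round(pwm$log_odds / 0.01)) * 0.01)
  # alpha 1 returns the minimum achievable score (tail mass 1)
  th1 <- exact_pvalue_threshold(pwm, alpha = 1)
  expect_equal(th1$threshold, min(round(pwm$log_odds / 0.01)) * 0.01)
  expect_equal(th1$tail_prob, 1)
  # collapse to one atom errors
  expect_error(pwm_score_distribution(pwm, granularity = 1000), "single atom")
  expect_error(exact_pvalue_threshold(pwm, alpha = 0), "alpha")
})

test_that("pvalue_of is non-increasing and thresholds tighten with alpha", {
  set.seed(5)
  pwm <- random_pwm(5)
  th <- exact_pvalue_threshold(pwm, 0.05)
  scores <- seq(-5, 5, by = 0.37)
  pv <- th$pvalue_of(scores)
  expect_true(all(diff(pv) <= 1e-12))
  alphas <- c(0.5, 0.1, 0.05, 0.01, 0.001)
  ths <- vapply(alphas, function(a) exact_pvalue_threshold(pwm, a)$threshold, 1)
  expect_true(all(diff(ths) >= 0))
})

test_that("scanning reports both strands in reference coordinates", {
  pwm <- ets_like_pwm() # consensus GGAAGC-ish, not palindromic
  cons <- pwm_consensus(pwm)
  seq <- paste0("TTTTT", cons, "TTTTT")
  hits <- scan_sequence(seq, pwm, alpha = 0.01)
  expect_true(any(hits$strand == "+" & hits$start == 5 & hits$end == 5 + nchar(cons)))

  # the reverse complement sequence has the mirror hit on the minus strand,
  # still addressed by the matched window's reference interval
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
  hits_rc <- scan_sequence(rc, pwm, alpha = 0.01)
  n <- nchar(seq)
  expect_equal(nrow(hits_rc), nrow(hits))
  for (i in seq_len(nrow(hits))) {
    j <- which(hits_rc$start == n - hits$end[i] &
                 hits_rc$strand == setdiff(c("+", "-"), hits$strand[i]))
    expect_length(j, 1)
    expect_equal(hits_rc$score[j], hits$score[i])
  }

  # N windows are skipped entirely
  expect_equal(nrow(scan_sequence(strrep("N", 50), pwm)), 0)
  # short sequences yield an empty frame, not an error
  expect_equal(nrow(scan_sequence("ACG", pwm)), 0)
  # hits come sorted by start with + before - at ties
  set.seed(3)
  long <- random_dna_string(2000)
  h <- scan_sequence(long, pwm, alpha = 0.05)
  expect_true(all(diff(h$start) >= 0))
  ties <- split(h$strand, h$start)
  expect_true(all(vapply(ties, function(s) identical(s, sort(s)), TRUE)))
})

test_that("scan p-values agree with the exact distribution", {
  set.seed(9)
  pwm <- random_pwm(4)
  seq <- random_dna_string(500)
  hits <- scan_sequence(seq, pwm, alpha = 1)
  th <- exact_pvalue_threshold(pwm, 0.5)
  expect_equal(hits$pvalue, unname(th$pvalue_of(hits$score)), tolerance = 1e-12)
})

test_that("IUPAC core matching expands degenerate codes", {
  expect_true(matches_core("GGAA", "GGAA"))
  expect_true(matches_core("CCTTTGATC", "SCTTTGATS"))
  expect_false(matches_core("ACTTTGATC", "SCTTTGATS"))
  expect_true(matches_core("TAATTA", "TAATTA"))
  expect_error(matches_core("GGA", "GGAA"), "length")
  expect_error(matches_core("GGAA", "GGXA"), "IUPAC")
})

test_that("JASPAR PFM files round-trip through the reader", {
  path <- write_tmp(c(
    ">MA0001.1 TESTMOTIF",
    "A [ 10  0  3 ]",
    "C [  0 12  3 ]",
    "G [  2  0  3 ]",
    "T [  0  0  3 ]",
    ">MA0002.1 BARE",
    "5 0", "0 5", "0 0", "0 0"
  ), ".pfm")
  pwms <- read_jaspar_pfm(path)
  expect_named(pwms, c("TESTMOTIF", "BARE"))
  expect_equal(unname(pwms$TESTMOTIF$counts[, 1]), c(10, 0, 2, 0))
  expect_equal(pwms$BARE$length, 2)
  expect_error(read_jaspar_pfm(write_tmp(c(">x", "1 2", "3 4"), ".pfm")), "4 count rows")
})
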