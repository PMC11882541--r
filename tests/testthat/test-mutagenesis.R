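test_that("an Ets core is overwritten by a restriction site", {
  seq <- "TTTTCAAGGAACGTACTTTT"
  hit <- tibble::tibble(start = 6, end = 12) # window AGGAAC
  plan <- design_core_disruption(seq, hit, "GGAA", c(BamHI = "GGATCC"),
                                 max_subs = 4)
  expect_true(plan$feasible)
  expect_true(plan$lost_core)
  expect_equal(nchar(plan$mutated_sequence), nchar(seq))
  expect_true(grepl("GGATCC", plan$mutated_sequence, fixed = TRUE))
  # the enzyme site sits at the recorded placement
  expect_equal(
    substr(plan$mutated_sequence, plan$placement + 1, plan$placement + 6),
    "GGATCC"
  )
  # no core match survives anywhere overlapping the original core
  win <- substr(plan$mutated_sequence, 5, 16)
  expect_false(any(vapply(1:(nchar(win) - 3), function(i) {
    matches_core(substr(win, i, i + 3), "GGAA")
  }, TRUE)))
  # substitutions change bases and are within budget
  expect_lte(plan$n_subs, 4)
  expect_true(all(plan$substitutions$ref_base != plan$substitutions$alt_base))
})

test_that("degenerate enzyme positions keep compliant reference bases", {
  # site 'GGWCC' (W = A/T): the A at the W position needs no substitution
  seq <- "AAAGGAACCAAA"
  hit <- tibble::tibble(start = 3, end = 9)
  plan <- design_core_disruption(seq, hit, "GGAA", c(Syn = "GGWCC"), max_subs = 3)
  expect_true(plan$feasible)
  expect_true(all(plan$substitutions$ref_base != plan$substitutions$alt_base))
  expect_true(matches_core(substr(plan$mutated_sequence, plan$placement + 1,
                                  plan$placement + 5), "GGWCC"))
})

test_that("infeasible or invalid disruption requests are signalled", {
  seq <- "TTTTCAAGGAACGTACTTTT"
  hit <- tibble::tibble(start = 6, end = 12)
  expect_error(
    design_core_disruption("TTTTTTTTTTTT", tibble::tibble(start = 2, end = 8),
                           "GGAA", c(BamHI = "GGATCC")),
    "no match to the core"
  )
  plan0 <- design_core_disruption(seq, hit, "GGAA", c(BamHI = "GGATCC"),
                                  max_subs = 0)
  expect_false(plan0$feasible)
  expect_false(plan0$accepted)
  expect_error(
    design_core_disruption("ACGGAA", tibble::tibble(start = 2, end = 6), "GGAA",
                           c(Long = strrep("GAATTC", 3))),
    "longer than"
  )
})

test_that("re-scanning detects gained and lost sites", {
  pwm <- ets_like_pwm()
  cons <- pwm_consensus(pwm)
  wt <- paste0("TTTTTT", cons, "TTTTTT")
  # identity: nothing gained or lost
  gl0 <- verify_no_gain(wt, wt, list(pwm))
  expect_equal(nrow(gl0$gained), 0)
  expect_equal(nrow(gl0$lost), 0)
  # destroying the site loses it without gains
  mut <- paste0("TTTTTT", strrep("T", nchar(cons)), "TTTTTT")
  gl1 <- verify_no_gain(wt, mut, list(pwm))
  expect_equal(nrow(gl1$gained), 0)
  expect_true(any(gl1$lost$start == 6 & gl1$lost$strand == "+"))
  # writing a consensus at a fresh offset is reported as gained
  wt2 <- strrep("T", 20)
  mut2 <- paste0("TT", cons, strrep("T", 18 - nchar(cons)))
  gl2 <- verify_no_gain(wt2, mut2, list(pwm))
  expect_true(any(gl2$gained$start == 2 & gl2$gained$strand == "+"))
  expect_error(verify_no_gain("ACGT", "ACG", list(pwm)), "length")
})

test_that("site spacing uses nearest edges with overlap collapsing to zero", {
  hits <- tibble::tibble(
    pwm = c("a", "b", "c"),
    start = c(10, 20, 22), end = c(14, 24, 30)
  )
  d <- pairwise_site_distance(hits)
  expect_equal(nrow(d), 3)
  expect_equal(d$distance_bp[d$pwm_i == "a" & d$pwm_j == "b"], 6)
  expect_equal(d$distance_bp[d$pwm_i == "b" & d$pwm_j == "c"], 0) # overlap
  expect_error(pairwise_site_distance(hits[1, ]), "two hits")
})

test_that("random disruption plans satisfy the full round-trip contract", {
  set.seed(77)
  pwms <- list(ets_like_pwm())
  enz <- enzyme_catalog()
  cores <- c("GGAA", "SCTTTGATS", "TAATTA")
  accepted <- 0
  for (i in 1:30) {
    core <- sample(cores, 1)
    inst <- paste(vapply(strsplit(core, "")[[1]], function(cc) {
      sample(crmscreen:::IUPAC[[cc]], 1)
    }, ""), collapse = "")
    flank <- 12
    seq <- paste0(random_dna_string(flank), inst, random_dna_string(flank))
    hit <- tibble::tibble(start = flank, end = flank + nchar(inst))
    plan <- design_core_disruption(seq, hit, core, enz, max_subs = 6,
                                   pwms = pwms)
    expect_true(plan$feasible)
    expect_true(plan$lost_core)
    expect_equal(nchar(plan$mutated_sequence), nchar(seq))
    expect_lte(plan$n_subs, 6)
    site <- plan$enzyme_site
    placed <- substr(plan$mutated_sequence, plan$placement + 1,
                     plan$placement + nchar(site))
    expect_true(matches_core(placed, site))
    if (plan$accepted) {
      accepted <- accepted + 1
      expect_equal(nrow(plan$gained_hits), 0)
    }
  }
  expect_gt(accepted, 15) # most random contexts admit a clean plan
})
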