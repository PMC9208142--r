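mk_table <- function(ids, peptides, scores, decoy, label) {
  psm_table(ids, peptides, "P1", scores, is_decoy = decoy, label = label)
}

test_that("spectrum pairing classifies match kinds and reallocations", {
  full <- mk_table(c("s1", "s2", "s3"),
                   c("AAAAAAAK", "CCCCCCCK", "DDDDDDDK"),
                   c(50, 30, 20), c(FALSE, TRUE, FALSE), "full")
  reduced <- mk_table(c("s1", "s2", "s4"),
                      c("AAAAAAAK", "EEEEEEEK", "FFFFFFFK"),
                      c(50, 22, 18), c(FALSE, FALSE, FALSE), "reduced")
  pairs <- pair_searches(full, reduced)
  expect_equal(nrow(pairs), 4L)
  p <- function(id) pairs[pairs$spectrum_id == id, ]
  expect_false(p("s1")$reallocated)            # same target both sides
  expect_true(p("s2")$reallocated)             # decoy -> target
  expect_equal(p("s2")$full_kind, "DECOY")
  expect_equal(p("s2")$reduced_kind, "TARGET")
  expect_equal(p("s3")$reduced_kind, "NO_MATCH")
  expect_equal(p("s4")$full_kind, "NO_MATCH")
  dup <- mk_table(c("s1", "s1"), c("AAAAAAAK", "CCCCCCCK"),
                  c(10, 9), FALSE, "full")
  expect_error(pair_searches(dup, reduced), "duplicate")
})

test_that("reallocation score summary counts directions by reduced kind", {
  full <- mk_table(c("s1", "s2", "s3"),
                   c("AAAAAAAK", "CCCCCCCK", "DDDDDDDK"),
                   c(50, 30, 20), c(FALSE, TRUE, FALSE), "full")
  reduced <- mk_table(c("s1", "s2", "s3"),
                      c("GGGGGGGK", "EEEEEEEK", "DDDDDDDK"),
                      c(45, 30, 25), c(FALSE, FALSE, FALSE), "reduced")
  chk <- reallocation_score_check(pair_searches(full, reduced))
  expect_equal(chk$counts["lower", "TARGET"], 1L)  # s1, 50 -> 45
  expect_equal(chk$counts["equal", "TARGET"], 1L)  # s2, 30 -> 30
  expect_equal(chk$n_target_score_gain, 0L)        # s3 not reallocated
})

test_that("additional identifications decompose into disjoint categories", {
  # hand-built cases mirroring the three documented rules
  full <- mk_table(c("s1", "s2", "s3"),
                   c("AAAAAAAK", "CCCCCCCK", "DDDDDDDK"),
                   c(37, 38, 36), c(FALSE, TRUE, FALSE), "full")
  reduced <- mk_table(c("s1", "s2", "s3"),
                      c("AAAAAAAK", "EEEEEEEK", "GGGGGGGK"),
                      c(37, 41, 36), c(FALSE, FALSE, FALSE), "reduced")
  br <- decompose_additional(pair_searches(full, reduced),
                             cutoff_full = 40, cutoff_reduced = 35)
  # s1: identical PSM, valid only under the lower reduced cutoff
  expect_equal(unname(br$spectra["lower_cutoff_no_realloc"]), 1L)
  # s2: decoy(38) -> target(41), 41 >= 40: a pure reallocation
  expect_equal(unname(br$spectra["pure_reallocation"]), 1L)
  # s3: target -> different target at 36 < 40: lower cutoff, reallocated
  expect_equal(unname(br$spectra["lower_cutoff_realloc_from_target"]), 1L)
  expect_equal(br$n_additional_spectra, 3L)
  expect_equal(sum(br$spectra), br$n_additional_spectra)
  expect_equal(sum(br$peptides), br$n_additional_peptides)
})

test_that("equal cutoffs leave only pure reallocations on simulated pairs", {
  for (seed in c(2, 5, 8)) {
    sim <- simulate_pair(sim_config(n_spectra = 800, seed = seed))
    pairs <- pair_searches(sim$full, sim$reduced)
    cf <- tdc_cutoff(sim$full, 0.01)$cutoff
    br <- decompose_additional(pairs, cf, cf)
    low <- grep("^lower", names(br$spectra))
    expect_equal(sum(br$spectra[low]), 0L)
    expect_equal(unname(br$spectra["pure_reallocation"]),
                 br$n_additional_spectra)
  }
})

test_that("breakdown categories sum on simulated pairs at native cutoffs", {
  for (seed in c(3, 7)) {
    sim <- simulate_pair(sim_config(n_spectra = 1500, seed = seed))
    pairs <- pair_searches(sim$full, sim$reduced)
    cf <- tdc_cutoff(sim$full, 0.01)$cutoff
    cr <- tdc_cutoff(sim$reduced, 0.01)$cutoff
    br <- decompose_additional(pairs, cf, cr)
    expect_equal(sum(br$spectra), br$n_additional_spectra)
    expect_equal(sum(br$peptides), br$n_additional_peptides)
    expect_gte(br$n_additional_spectra, br$n_additional_peptides)
  }
})

test_that("subset-reduced searches never gain score on target reallocation", {
  for (seed in 1:5) {
    sim <- simulate_pair(sim_config(n_spectra = 1000, seed = seed))
    chk <- reallocation_score_check(pair_searches(sim$full, sim$reduced))
    expect_equal(chk$n_target_score_gain, 0L)
    expect_equal(sum(chk$counts["higher", ]), 0L)
  }
})

test_that("valid-match fate accounting under a transferred cutoff", {
  full <- mk_table(c("s1", "s2", "s3"),
                   c("AAAAAAAK", "CCCCCCCK", "DDDDDDDK"),
                   c(50, 45, 48), c(FALSE, FALSE, TRUE), "full")
  # s1 same valid; s2 reallocated below cutoff; s3 decoy absent
  reduced <- mk_table(c("s1", "s2"),
                      c("AAAAAAAK", "EEEEEEEK"),
                      c(50, 20), c(FALSE, FALSE), "reduced")
  loss <- decoy_loss_analysis(pair_searches(full, reduced), cutoff_full = 40)
  expect_equal(unname(loss$fate["same_valid", "TARGET"]), 1L)
  expect_equal(unname(loss$fate["realloc_invalid", "TARGET"]), 1L)
  expect_equal(unname(loss$fate["no_match", "DECOY"]), 1L)
  expect_equal(unname(loss$net_loss_pct["DECOY"]), 100)
  expect_equal(unname(loss$net_loss_pct["TARGET"]), 50)
  # identity: zero loss
  same <- decoy_loss_analysis(pair_searches(full, full), cutoff_full = 40)
  expect_equal(unname(same$net_loss_pct["TARGET"]), 0)
  expect_equal(unname(same$net_loss_pct["DECOY"]), 0)
  # nothing valid: empty table
  none <- decoy_loss_analysis(pair_searches(full, reduced), cutoff_full = 99)
  expect_true(all(none$fate == 0))
})

test_that("valid decoys are lost in the reduced search at the full cutoff", {
  sim <- simulate_pair(sim_config(n_spectra = 4000, seed = 31))
  cf <- tdc_cutoff(sim$full, 0.01)$cutoff
  loss <- decoy_loss_analysis(pair_searches(sim$full, sim$reduced), cf)
  expect_gt(unname(loss$net_loss_pct["DECOY"]),
            unname(loss$net_loss_pct["TARGET"]))
  expect_gt(unname(loss$net_loss_pct["DECOY"]), 0)
})
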