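# Top-clone ranking, four-way new-clone classification, frequency-increase
# attribution, tracking-set selection and longitudinal tracking.

test_that("top_clones ranks by count with a deterministic tie-break", {
  rep <- make_rep(c(10, 5, 5, 2, 1),
                  nt = c("TTT", "TGA", "TAA", "CCC", "AAA"))
  top <- top_clones(rep, n = 3, level = "nt")
  expect_equal(top$nt_seq, c("TTT", "TAA", "TGA"))  # tie at 5 broken lexicographically
  expect_equal(top$rank, 1:3)
  expect_equal(nrow(top_clones(rep, n = 100)), 5)   # n >= S returns all, ranked
  expect_equal(top_clones(rep, n = 1)$nt_seq, "TTT")
  expect_error(top_clones(rep, n = 0), "positive")
})

test_that("classification assigns the four categories per precedence on a hand-built pair", {
  baseline <- make_rep(c(50, 30), nt = c("AACAACGCT", "GGTGGTTAA"),
                       aa = c("CASSAF", "CASSBF"))
  followup <- make_rep(c(40, 30, 20, 10),
                       nt = c("AACAACGCT",  # same nt as baseline -> increased_nt
                              "AACAATGGG",  # new nt, aa CASSBF verbatim -> new_nt
                              "CCCCCCCCC",  # aa CASSCF at distance 1 of CASSAF -> new_similar_aa
                              "TTTTTTTTT"), # aa CGGWGT unrelated -> new_aa
                       aa = c("CASSAF", "CASSBF", "CASSCF", "CGGWGT"))
  # distances verified against the DP oracle
  expect_equal(lev_dp("CASSCF", "CASSAF"), 1)
  expect_true(lev_dp("CGGWGT", "CASSAF") > 1 && lev_dp("CGGWGT", "CASSBF") > 1)

  cls <- classify_new_clones(baseline, followup, n = 4)
  expect_equal(as.character(cls$category),
               c("increased_nt", "new_nt", "new_similar_aa", "new_aa"))
  expect_equal(cls$baseline_freq, c(50 / 80, 0, 0, 0))
  expect_equal(cls$delta_freq, cls$followup_freq - cls$baseline_freq)
  expect_equal(attr(cls, "n_new_tcrs"), 2)  # CASSCF + CGGWGT
})

test_that("identical repertoires classify as increased_nt with zero deltas; disjoint ones as new_aa", {
  rep <- make_rep(c(5, 3, 2), aa = c("CAAAF", "CCCCF", "CWWWF"))
  same <- classify_new_clones(rep, rep, n = 10)
  expect_true(all(same$category == "increased_nt"))
  expect_equal(same$delta_freq, rep(0, 3))

  other <- make_rep(c(4, 4), nt = c("GGGGGG", "CCCCCC"),
                    aa = c("CYYYYYYF", "CHHHHHHF"))
  dis <- classify_new_clones(rep, other, n = 10)
  expect_true(all(dis$category == "new_aa"))
})

test_that("classification is a partition honoring the precedence order", {
  set.seed(21)
  for (i in seq_len(10)) {
    baseline <- random_repertoire(n = 30)
    followup <- random_repertoire(n = 40)
    # overlap some clones so several categories occur
    followup$clones$nt_seq[1:10] <- baseline$clones$nt_seq[1:10]
    followup$clones$aa_seq[1:10] <- baseline$clones$aa_seq[1:10]
    followup <- repertoire(followup$clones[, c("nt_seq", "aa_seq", "count", "productive")],
                           sample_id = "f", patient_id = "p1", timepoint = "cycle7")
    cls <- classify_new_clones(baseline, followup, n = 25)
    expect_equal(nrow(cls), min(25, nrow(followup$clones)))
    expect_false(any(is.na(cls$category)))          # exhaustive
    # precedence: nt match always beats aa-level labels
    base_nt <- baseline$clones$nt_seq
    base_aa <- baseline$clones$aa_seq
    expect_true(all((cls$nt_seq %in% base_nt) == (cls$category == "increased_nt")))
    expect_true(all((!cls$nt_seq %in% base_nt & cls$aa_seq %in% base_aa) ==
                      (cls$category == "new_nt")))
    # new_* rows were never detected at baseline at the nucleotide level
    expect_true(all(cls$baseline_freq[cls$category != "increased_nt"] == 0))
  }
})

test_that("frequency-increase attribution clamps decreases and conserves the total", {
  baseline <- make_rep(c(10, 80, 10), nt = c("AAA", "CCC", "GGG"),
                       aa = c("CAAF", "CCCF", "CGGF"))
  followup <- make_rep(c(30, 60, 10), nt = c("AAA", "CCC", "TTT"),
                       aa = c("CAAF", "CCCF", "CCCF"))
  cls <- classify_new_clones(baseline, followup, n = 3)
  att <- attribute_frequency_increase(cls)
  expect_equal(as.character(att$category),
               c("increased_nt", "new_nt", "new_similar_aa", "new_aa"))
  # increased_nt: clone AAA gained 0.3 - 0.1; clone CCC decreased -> contributes 0
  expect_equal(att$total_increase[att$category == "increased_nt"], 0.2)
  expect_equal(att$total_increase[att$category == "new_nt"], 0.1)
  expect_equal(attr(att, "grand_total"), sum(pmax(cls$delta_freq, 0)))

  # single new clone at 0.02 -> only its category carries mass
  one <- classify_new_clones(make_rep(c(98)), make_rep(c(98, 2),
                             nt = c("TGTAAATTC", "TGTCCCTTC"),
                             aa = c("CASSAF", "CWGYEQF")), n = 100)
  att1 <- attribute_frequency_increase(one)
  expect_equal(att1$total_increase[att1$category == "new_aa"], 0.02)
})

test_that("tracking sets honor top-k, new-only restriction and degenerate cases", {
  base <- make_rep(c(50, 30, 20), nt = c("AAA", "CCC", "GGG"),
                   aa = c("CAAF", "CCCF", "CGGF"), timepoint = "baseline")
  anchor <- make_rep(c(40, 25, 20, 15), nt = c("AAA", "TTT", "CCC", "ACG"),
                     aa = c("CAAF", "CTTF", "CCCF", "CAGF"),
                     timepoint = "cycle7", sample_id = "s2")
  tc <- timecourse(list(base, anchor))
  expect_equal(select_tracking_set(tc, anchor = "cycle7", k = 2),
               c("AAA", "TTT"))
  expect_equal(select_tracking_set(tc, anchor = "cycle7", k = 7, new_only = TRUE) |>
                 suppressWarnings(),
               c("TTT", "ACG"))
  expect_warning(select_tracking_set(tc, anchor = "cycle7", k = 7),
                 "available for tracking")
  expect_error(select_tracking_set(tc, anchor = "cycle18"), "not present")

  # no new clones at the anchor -> empty set with a warning
  tc_same <- timecourse(list(base, make_rep(c(5, 3, 2),
                                            nt = c("AAA", "CCC", "GGG"),
                                            aa = c("CAAF", "CCCF", "CGGF"),
                                            timepoint = "cycle7", sample_id = "s3")))
  expect_warning(keys <- select_tracking_set(tc_same, anchor = "cycle7",
                                             new_only = TRUE),
                 "no new clones")
  expect_equal(keys, character(0))
})

test_that("tracking matrices carry zero frequencies for absences and flag drops", {
  base <- make_rep(c(90, 10), nt = c("AAA", "CCC"), aa = c("CAAF", "CCCF"),
                   timepoint = "baseline")
  mid <- make_rep(c(50, 10, 40), nt = c("AAA", "CCC", "TTT"),
                  aa = c("CAAF", "CCCF", "CTTF"), timepoint = "cycle7",
                  sample_id = "s2")
  late <- make_rep(c(98, 2), nt = c("AAA", "TTT"), aa = c("CAAF", "CTTF"),
                   timepoint = "progression", sample_id = "s3")
  tc <- timecourse(list(base, mid, late))
  tt <- track_clones(tc, c("TTT", "CCC"))
  expect_equal(tt$baseline, c(0, 0.1))            # absent at baseline -> 0
  expect_equal(tt$cycle7, c(0.4, 0.1))
  expect_equal(tt$progression, c(0.02, 0))
  expect_true(tt$disappeared[tt$nt_seq == "CCC"])
  expect_true(tt$dramatic_decrease[tt$nt_seq == "TTT"])  # 0.4 -> 0.02 is > 10-fold

  # single-timepoint course: one frequency column, no flags possible
  tc1 <- timecourse(list(base))
  tt1 <- track_clones(tc1, "AAA")
  expect_equal(tt1$baseline, 0.9)
  expect_false(tt1$disappeared)

  # cumulative top-clone frequency per sample
  cum <- cumulative_top_frequency(tc, k = 2)
  expect_equal(cum$cumulative_freq[1], 1)          # only 2 clones at baseline
  expect_equal(cum$cumulative_freq[2], 0.9)        # 0.5 + 0.4 at cycle7
})

test_that("new-clone count series reports every follow-up against the first sample", {
  base <- make_rep(c(50, 50), nt = c("AAA", "CCC"), aa = c("CAAAF", "CCCCF"))
  f1 <- make_rep(c(60, 40), nt = c("AAA", "TTT"), aa = c("CAAAF", "CWWWF"),
                 timepoint = "radiotherapy", sample_id = "f1")
  f2 <- make_rep(c(30, 70), nt = c("AAA", "GGG"), aa = c("CAAAF", "CHHHF"),
                 timepoint = "cycle7", sample_id = "f2")
  series <- new_clone_count_series(timecourse(list(base, f1, f2)), n = 100)
  expect_equal(series$timepoint, c("radiotherapy", "cycle7"))
  expect_equal(series$n_new_tcrs, c(1, 1))
  expect_equal(series$n_increased_nt, c(1, 1))
})
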