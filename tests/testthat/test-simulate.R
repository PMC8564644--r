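# Synthetic repertoire generator: determinism, distributional shape,
# construction invariants, planted-event fidelity, fixture round-trips.

small_scenario <- function(seed = 1, ...) {
  simulation_scenario(n_clones = 400, library_sizes = 30000,
                      n_expanded = 5, expansion_fold = 10,
                      n_new = 6, new_freqs = c(0.02, 0.012, 0.008),
                      frac_similar = 1 / 6, frac_new_nt = 1 / 6,
                      seed = seed, ...)
}

test_that("identical scenario and seed reproduce byte-identical repertoires", {
  b1 <- simulate_baseline(small_scenario(seed = 42))
  b2 <- simulate_baseline(small_scenario(seed = 42))
  expect_identical(b1$clones, b2$clones)
  s1 <- simulate_timecourse(b1, small_scenario(seed = 42))
  s2 <- simulate_timecourse(b2, small_scenario(seed = 42))
  expect_identical(lapply(s1$timecourse$repertoires, `[[`, "clones"),
                   lapply(s2$timecourse$repertoires, `[[`, "clones"))
  expect_identical(s1$truth, s2$truth)
  # a different seed gives different data
  b3 <- simulate_baseline(small_scenario(seed = 43))
  expect_false(identical(b1$clones, b3$clones))
})

test_that("power-law baselines are heavy-tailed and convergent variants translate identically", {
  sc <- simulation_scenario(n_clones = 5000, library_sizes = 100000,
                            exponent = 2, n_convergent_nt = 3,
                            convergent_prob = 0.2, seed = 7)
  b <- simulate_baseline(sc)
  freqs <- b$clones$freq
  expect_gt(max(freqs), 50 * stats::median(freqs))   # heavy tail
  agg <- aa_clonotypes(b)
  expect_gt(max(agg$n_nt_variants), 1)
  expect_lte(max(agg$n_nt_variants), 3)
  # synonymous variants genuinely translate to their clonotype's CDR3
  multi <- agg$aa_seq[agg$n_nt_variants >= 2][1:10]
  for (aa in multi) {
    nts <- b$clones$nt_seq[b$clones$aa_seq == aa]
    trans <- as.character(Biostrings::translate(Biostrings::DNAStringSet(nts)))
    expect_true(all(trans == aa))
  }
  # CDR3-like shape: starts with C, ends with F, lengths 10-20
  expect_true(all(grepl("^C.*F$", b$clones$aa_seq)))
  expect_true(all(nchar(b$clones$aa_seq) %in% 10:20))
})

test_that("null scenarios are plain multinomial resamples of baseline", {
  sc <- simulation_scenario(n_clones = 400, library_sizes = 30000,
                            n_expanded = 0, n_new = 0, seed = 3)
  b <- simulate_baseline(sc)
  sim <- simulate_timecourse(b, sc)
  truth <- sim$truth
  expect_true(all(truth$category == "persistent"))
  # expected frequencies unchanged across timepoints
  expect_equal(truth$freq_radiotherapy, truth$freq_baseline, tolerance = 1e-12)
  expect_equal(truth$freq_cycle7, truth$freq_baseline, tolerance = 1e-12)
})

test_that("planted clones land near their target frequencies with correct construction", {
  sc <- small_scenario(seed = 11)
  b <- simulate_baseline(sc)
  sim <- simulate_timecourse(b, sc)
  truth <- sim$truth
  planted <- truth[truth$category %in% c("new_aa", "new_similar_aa", "new_nt"), ]
  expect_equal(nrow(planted), 6)
  expect_equal(sum(planted$category == "new_similar_aa"), 1)
  expect_equal(sum(planted$category == "new_nt"), 1)

  rt <- sim$timecourse$repertoires[["radiotherapy"]]
  obs <- rt$clones$count[match(planted$nt_seq, rt$clones$nt_seq)]
  obs[is.na(obs)] <- 0
  n <- rt$total_count
  for (i in seq_len(nrow(planted))) {
    f <- planted$freq_radiotherapy[i]
    sd3 <- 3 * sqrt(n * f * (1 - f))
    expect_lt(abs(obs[i] - n * f), sd3 + 1)      # within 3 binomial SDs
  }

  base_aa <- unique(b$clones$aa_seq)
  sim_aa <- planted$aa_seq[planted$category == "new_similar_aa"]
  expect_false(sim_aa %in% base_aa)
  expect_equal(min(utils::adist(sim_aa, base_aa)), 1)       # distance exactly 1
  newnt <- planted[planted$category == "new_nt", ]
  expect_true(newnt$aa_seq %in% base_aa)                     # aa existed
  expect_false(newnt$nt_seq %in% attr(b, "sim_truth")$nt_seq)  # nt genuinely new
  unrel <- planted$aa_seq[planted$category == "new_aa"]
  expect_true(all(apply(utils::adist(unrel, base_aa), 1, min) >= 2))
})

test_that("per-sample frequencies always sum to one", {
  sc <- small_scenario(seed = 13)
  sim <- simulate_timecourse(simulate_baseline(sc), sc)
  for (rep in sim$timecourse$repertoires) {
    expect_equal(sum(rep$clones$freq), 1, tolerance = 1e-9)
  }
  expected_cols <- paste0("freq_", sc$timepoints)
  for (col in expected_cols[-1]) {
    expect_equal(sum(sim$truth[[col]]), 1, tolerance = 1e-9)
  }
})

test_that("expansion scenarios reduce subsampled Shannon diversity", {
  sc <- simulation_scenario(n_clones = 2000, library_sizes = 100000,
                            n_expanded = 20, expansion_fold = 10,
                            n_new = 0, seed = 17)
  sim <- simulate_timecourse(simulate_baseline(sc), sc)
  h <- vapply(sim$timecourse$repertoires, function(r)
    subsampled_renyi(r, depth = 70000, permutations = 10, seed = 1,
                     alphas = 1)$H, numeric(1))
  expect_lt(h[["radiotherapy"]], h[["baseline"]])
})

test_that("fixtures round-trip losslessly and include a usable sample sheet", {
  sc <- small_scenario(seed = 19)
  sim <- simulate_timecourse(simulate_baseline(sc), sc)
  dir <- withr::local_tempdir()
  files <- export_fixtures(sim$timecourse, sim$truth, dir)
  expect_true(file.exists(files$sample_sheet))
  expect_true(file.exists(files$truth))
  courses <- load_timecourses(files$sample_sheet)
  tc2 <- courses[[sim$timecourse$patient_id]]
  expect_equal(tc2$timepoints, sim$timecourse$timepoints)
  for (tp in sim$timecourse$timepoints) {
    key <- function(r) r$clones[order(r$clones$nt_seq),
                                c("nt_seq", "aa_seq", "count")]
    expect_equal(key(tc2$repertoires[[tp]]),
                 key(sim$timecourse$repertoires[[tp]]))
  }
  # both dialects of the same sample parse to equal repertoires
  s1 <- read_immunoseq(files[[1]][["immunoseq"]])
  s2 <- read_airr(files[[1]][["airr"]])
  expect_equal(s1$clones[, c("nt_seq", "aa_seq", "count")],
               s2$clones[, c("nt_seq", "aa_seq", "count")])
  # truth table has one row per simulated clone
  truth_back <- readr::read_tsv(files$truth, show_col_types = FALSE)
  expect_equal(nrow(truth_back), nrow(sim$truth))
  expect_false(anyDuplicated(truth_back$nt_seq) > 0)
})

test_that("infeasible scenarios are rejected up front", {
  expect_error(simulation_scenario(n_new = 30, new_freqs = 0.05),
               "well below 1")
  expect_error(simulation_scenario(n_clones = 1000, library_sizes = 100),
               "library_sizes")
  expect_error(simulation_scenario(timepoints = "baseline", n_new = 2,
                                   new_at = "cycle7"),
               "new_at")
})

test_that("a shallower baseline can only increase the new-clone count", {
  # library-size caveat: rare baseline clones drop below detection when the
  # baseline is downsampled, so apparent novelty grows monotonically
  sc <- simulation_scenario(n_clones = 3000, library_sizes = 100000,
                            n_expanded = 10, n_new = 5, seed = 23)
  sim <- simulate_timecourse(simulate_baseline(sc), sc)
  base <- sim$timecourse$repertoires[["baseline"]]
  rt <- sim$timecourse$repertoires[["radiotherapy"]]
  full_cls <- classify_new_clones(base, rt, n = 100)

  set.seed(23)
  shallow_counts <- tcrdyn:::subsample_counts(base$clones$count,
                                              round(base$total_count / 10))
  keep <- shallow_counts > 0
  shallow <- repertoire(
    data.frame(nt_seq = base$clones$nt_seq[keep],
               aa_seq = base$clones$aa_seq[keep],
               count = shallow_counts[keep], productive = TRUE),
    sample_id = "shallow", patient_id = base$patient_id,
    timepoint = "baseline")
  shallow_cls <- classify_new_clones(shallow, rt, n = 100)
  n_new <- function(cls) sum(cls$category %in% c("new_aa", "new_similar_aa"))
  expect_gte(n_new(shallow_cls), n_new(full_cls))
})
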