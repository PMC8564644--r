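# Synthetic repertoire time courses with planted ground truth.
#
# The generator emulates the statistical structure of bulk TCR-beta
# repertoires from treated patients: heavy-tailed clone sizes, several
# nucleotide rearrangements converging on one amino-acid CDR3, expansion and
# contraction of chosen clones between timepoints, emergence of genuinely
# new clones (unrelated, distance-1 similar, or new nucleotide variants of
# existing clonotypes), and multinomial sequencing noise at each timepoint's
# library size.

aa_alphabet <- function() {
  setdiff(unique(unname(Biostrings::GENETIC_CODE)), "*")
}

codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

# Random CDR3-like amino-acid strings: length 10-20 (mode ~14-15), starting
# C and ending F, middle residues uniform over the 20 standard amino acids.
random_cdr3_aa <- function(n) {
  lens <- sample(10:20, n, replace = TRUE, prob = stats::dnorm(10:20, 14.5, 2))
  aa <- aa_alphabet()
  mid_len <- lens - 2L
  letters_all <- sample(aa, sum(mid_len), replace = TRUE)
  grp <- rep.int(seq_len(n), mid_len)
  mids <- vapply(split(letters_all, grp), paste, character(1), collapse = "")
  paste0("C", mids, "F")
}

# One random reverse translation per amino-acid string (uniform codon
# choice). Vectorized: codons are drawn residue-class by residue-class over
# the flattened residue vector, then regrouped per sequence.
reverse_translate <- function(aa_seqs) {
  if (length(aa_seqs) == 0) return(character(0))
  ct <- codon_table()
  lens <- nchar(aa_seqs)
  chars <- strsplit(paste(aa_seqs, collapse = ""), "")[[1]]
  codons <- character(length(chars))
  for (letter in unique(chars)) {
    idx <- which(chars == letter)
    codons[idx] <- sample(ct[[letter]], length(idx), replace = TRUE)
  }
  grp <- rep.int(seq_along(aa_seqs), lens)
  unname(vapply(split(codons, grp), paste, character(1), collapse = ""))
}

#' Define a repertoire simulation scenario
#'
#' Collects the parameters of one synthetic study: baseline richness and
#' clone-size law, per-timepoint library sizes, which dynamics to plant
#' (expansion, contraction, new clones of each flavor), and the seed that
#' fully determines the output.
#'
#' Defaults describe a typical treated-patient time course at this assay's
#' scale: 20 000 baseline amino-acid clonotypes with discrete power-law
#' sizes (exponent 2.2, giving top clones in the percent range), 200 000
#' templates per library, a 10-fold expansion of the 200 most abundant
#' clones from the second timepoint on, and 8 new clones planted at the
#' second timepoint at frequencies 0.5-2% (roughly 15% distance-1 similar
#' to baseline, 15% new nucleotide variants of baseline clonotypes, the
#' rest unrelated), decaying 20-fold per subsequent timepoint.
#'
#' @param n_clones number of baseline amino-acid clonotypes.
#' @param size_distribution `"power_law"` or `"lognormal"`.
#' @param exponent power-law exponent of the clone-size law.
#' @param meanlog,sdlog log-normal parameters (used when
#'   `size_distribution = "lognormal"`).
#' @param timepoints ordered character vector of timepoint labels.
#' @param library_sizes template count per timepoint (recycled if scalar).
#' @param n_expanded,expansion_fold how many of the most abundant baseline
#'   clones expand, and by what factor, at follow-up timepoints.
#' @param n_contracted,contraction_fold clones (ranked after the expanded
#'   ones) whose expected frequency is divided by `contraction_fold`.
#' @param n_new number of new clones planted at `new_at`.
#' @param new_freqs target frequencies of the new clones (recycled to
#'   `n_new`); their sum must stay well below 1.
#' @param frac_similar fraction of new clones built at Levenshtein distance 1
#'   from an existing baseline amino-acid CDR3.
#' @param frac_new_nt fraction of new clones that are new nucleotide variants
#'   of an existing baseline clonotype.
#' @param new_at timepoint label at which new clones appear (default the
#'   second timepoint).
#' @param new_decay multiplicative factor applied to new-clone frequencies at
#'   each timepoint after `new_at` (emulates disappearance or dramatic
#'   decrease of treatment-induced clones).
#' @param revert_at_progression drop planted expansions at a timepoint
#'   labelled `"progression"` (diversity rebounds at progression).
#' @param n_convergent_nt maximum nucleotide variants per baseline clonotype.
#' @param convergent_prob per-extra-variant probability (binomial) that a
#'   clonotype carries additional synonymous variants.
#' @param patient_id patient label for the simulated course.
#' @param seed integer seed; together with the scenario it fully determines
#'   the simulated data.
#' @return a list of class `sim_scenario`.
#' @export
simulation_scenario <- function(n_clones = 20000,
                                size_distribution = c("power_law", "lognormal"),
                                exponent = 2.2, meanlog = 0, sdlog = 2,
                                timepoints = c("baseline", "radiotherapy", "cycle7"),
                                library_sizes = 200000,
                                n_expanded = 200, expansion_fold = 10,
                                n_contracted = 0, contraction_fold = 10,
                                n_new = 8,
                                new_freqs = c(0.02, 0.012, 0.008, 0.005),
                                frac_similar = 0.15, frac_new_nt = 0.15,
                                new_at = timepoints[min(2, length(timepoints))],
                                new_decay = 0.05,
                                revert_at_progression = TRUE,
                                n_convergent_nt = 3, convergent_prob = 0.05,
                                patient_id = "sim01", seed = 1) {
  size_distribution <- match.arg(size_distribution)
  stopifnot(n_clones >= 2, length(timepoints) >= 1, !anyDuplicated(timepoints),
            exponent > 1, expansion_fold > 0, contraction_fold >= 1,
            n_expanded >= 0, n_contracted >= 0, n_new >= 0,
            frac_similar >= 0, frac_new_nt >= 0, frac_similar + frac_new_nt <= 1,
            new_decay >= 0, n_convergent_nt >= 1)
  library_sizes <- rep_len(as.numeric(library_sizes), length(timepoints))
  names(library_sizes) <- timepoints
  if (any(library_sizes < n_clones)) {
    stop("library_sizes should exceed n_clones so most clones are observable",
         call. = FALSE)
  }
  new_freqs <- if (n_new > 0) rep_len(new_freqs, n_new) else numeric(0)
  if (sum(new_freqs) >= 0.5) {
    stop("planted new-clone frequencies sum to ", sum(new_freqs),
         "; must stay well below 1", call. = FALSE)
  }
  if (n_new > 0 && !new_at %in% timepoints) {
    stop("new_at ('", new_at, "') is not one of the scenario timepoints",
         call. = FALSE)
  }
  structure(
    list(n_clones = n_clones, size_distribution = size_distribution,
         exponent = exponent, meanlog = meanlog, sdlog = sdlog,
         timepoints = timepoints, library_sizes = library_sizes,
         n_expanded = n_expanded, expansion_fold = expansion_fold,
         n_contracted = n_contracted, contraction_fold = contraction_fold,
         n_new = n_new, new_freqs = new_freqs,
         frac_similar = frac_similar, frac_new_nt = frac_new_nt,
         new_at = new_at, new_decay = new_decay,
         revert_at_progression = revert_at_progression,
         n_convergent_nt = n_convergent_nt, convergent_prob = convergent_prob,
         patient_id = patient_id, seed = seed),
    class = "sim_scenario")
}

# Draw positive clone weights from the scenario's size law.
draw_weights <- function(n, scenario) {
  if (scenario$size_distribution == "power_law") {
    # inverse-CDF sample of a Pareto tail P(W > w) ~ w^-(exponent - 1)
    stats::runif(n)^(-1 / (scenario$exponent - 1))
  } else {
    stats::rlnorm(n, scenario$meanlog, scenario$sdlog)
  }
}

#' Simulate a baseline repertoire
#'
#' Generates `n_clones` distinct CDR3 amino-acid clonotypes, gives each one
#' or more distinct synonymous nucleotide rearrangements (uniform codon
#' choice under the standard genetic code), draws clone weights from the
#' scenario's heavy-tailed size law and samples template counts
#' multinomially at the baseline library size.
#'
#' @param scenario a [simulation_scenario()].
#' @return a [repertoire()] with attribute `sim_truth`: a tibble of the true
#'   underlying frequencies (`nt_seq`, `aa_seq`, `true_freq`).
#' @export
simulate_baseline <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  with_seed(derive_seed(scenario$seed, "baseline"), {
    aa <- unique(random_cdr3_aa(scenario$n_clones))
    while (length(aa) < scenario$n_clones) {
      aa <- unique(c(aa, random_cdr3_aa(scenario$n_clones - length(aa))))
    }
    n_var <- 1L + stats::rbinom(scenario$n_clones,
                                scenario$n_convergent_nt - 1L,
                                scenario$convergent_prob)
    aa_all <- rep.int(aa, n_var)
    nt_all <- reverse_translate(aa_all)
    dup <- duplicated(nt_all)
    while (any(dup)) {  # resample colliding synonymous variants
      nt_all[dup] <- reverse_translate(aa_all[dup])
      dup <- duplicated(nt_all)
    }
    w <- draw_weights(length(nt_all), scenario)
    w <- w / sum(w)
    counts <- as.numeric(stats::rmultinom(1, scenario$library_sizes[1], w))
    keep <- counts > 0
    rep <- repertoire(
      tibble::tibble(nt_seq = nt_all[keep], aa_seq = aa_all[keep],
                     count = counts[keep], productive = TRUE),
      sample_id = paste(scenario$patient_id, scenario$timepoints[1], sep = "_"),
      patient_id = scenario$patient_id, timepoint = scenario$timepoints[1])
    attr(rep, "sim_truth") <- tibble::tibble(nt_seq = nt_all, aa_seq = aa_all,
                                             true_freq = w)
    rep
  })
}

# Construct the planted new clones for a scenario against a baseline truth
# table. Categories: new_similar_aa (distance 1 from a baseline CDR3),
# new_nt (new synonymous variant of a baseline clonotype), new_aa
# (unrelated: no baseline CDR3 within distance 1).
make_new_clones <- function(truth, scenario) {
  n_new <- scenario$n_new
  if (n_new == 0) {
    return(tibble::tibble(nt_seq = character(0), aa_seq = character(0),
                          category = character(0), target_freq = numeric(0)))
  }
  base_aa <- unique(truth$aa_seq)
  base_nt <- truth$nt_seq
  aa_set <- aa_alphabet()
  n_similar <- round(scenario$frac_similar * n_new)
  n_newnt <- min(round(scenario$frac_new_nt * n_new), n_new - n_similar)
  n_unrel <- n_new - n_similar - n_newnt

  similar_aa <- character(0)
  while (length(similar_aa) < n_similar) {
    src <- sample(base_aa, 1)
    pos <- sample(2:(nchar(src) - 1), 1)
    repl <- sample(setdiff(aa_set, substr(src, pos, pos)), 1)
    cand <- paste0(substr(src, 1, pos - 1), repl,
                   substr(src, pos + 1, nchar(src)))
    if (!cand %in% base_aa && !cand %in% similar_aa) {
      similar_aa <- c(similar_aa, cand)
    }
  }
  newnt_aa <- if (n_newnt > 0) sample(base_aa, n_newnt) else character(0)
  unrel_aa <- character(0)
  while (length(unrel_aa) < n_unrel) {
    cand <- unique(random_cdr3_aa(max(2 * (n_unrel - length(unrel_aa)), 4)))
    cand <- cand[!cand %in% base_aa & !cand %in% unrel_aa &
                   !has_d1_neighbor(cand, base_aa)]
    unrel_aa <- c(unrel_aa, cand)
  }
  unrel_aa <- unrel_aa[seq_len(n_unrel)]
  aa_new <- c(similar_aa, newnt_aa, unrel_aa)
  nt_new <- reverse_translate(aa_new)
  clash <- nt_new %in% base_nt | duplicated(nt_new)
  while (any(clash)) {
    nt_new[clash] <- reverse_translate(aa_new[clash])
    clash <- nt_new %in% base_nt | duplicated(nt_new)
  }
  tibble::tibble(
    nt_seq = nt_new, aa_seq = aa_new,
    category = c(rep("new_similar_aa", n_similar), rep("new_nt", n_newnt),
                 rep("new_aa", n_unrel)),
    target_freq = scenario$new_freqs)
}

#' Simulate a repertoire time course with planted dynamics
#'
#' Starting from a baseline repertoire, constructs each follow-up timepoint
#' by (i) multiplying the expected frequencies of the planted expanded
#' clones by `expansion_fold` (and dividing contracted clones by
#' `contraction_fold`), (ii) injecting the scenario's new clones at their
#' target frequencies at `new_at` (decaying by `new_decay` per later
#' timepoint), renormalizing the pre-existing clones to the remaining mass,
#' and (iii) drawing template counts multinomially at the timepoint's
#' library size.
#'
#' @param baseline a repertoire from [simulate_baseline()].
#' @param scenario the same [simulation_scenario()].
#' @return a list with `timecourse` (a [timecourse()]) and `truth` (a tibble:
#'   one row per simulated clone with its planted `category` — `persistent`,
#'   `expanded`, `contracted`, `new_aa`, `new_similar_aa` or `new_nt` — and
#'   one expected-frequency column `freq_<timepoint>` per timepoint).
#' @export
simulate_timecourse <- function(baseline, scenario) {
  stopifnot(is_repertoire(baseline), inherits(scenario, "sim_scenario"))
  truth <- attr(baseline, "sim_truth")
  if (is.null(truth)) stop("baseline lacks simulation truth; use simulate_baseline()",
                           call. = FALSE)
  tps <- scenario$timepoints
  with_seed(derive_seed(scenario$seed, "timecourse"), {
    ord <- order(-truth$true_freq)
    expanded_idx <- ord[seq_len(min(scenario$n_expanded, nrow(truth)))]
    remaining <- setdiff(ord, expanded_idx)
    contracted_idx <- remaining[seq_len(min(scenario$n_contracted, length(remaining)))]
    category <- rep("persistent", nrow(truth))
    category[expanded_idx] <- "expanded"
    category[contracted_idx] <- "contracted"
    newc <- make_new_clones(truth, scenario)

    all_clones <- tibble::tibble(
      nt_seq = c(truth$nt_seq, newc$nt_seq),
      aa_seq = c(truth$aa_seq, newc$aa_seq),
      category = c(category, newc$category))
    n_base <- nrow(truth)
    expected <- matrix(0, nrow(all_clones), length(tps),
                       dimnames = list(NULL, tps))
    reps <- vector("list", length(tps))
    reps[[1]] <- baseline
    expected[seq_len(n_base), 1] <- truth$true_freq
    new_at_i <- if (scenario$n_new > 0) match(scenario$new_at, tps) else NA_integer_

    for (ti in seq_along(tps)[-1]) {
      tp <- tps[ti]
      w <- truth$true_freq
      apply_dynamics <- !(scenario$revert_at_progression && tp == "progression")
      if (apply_dynamics) {
        w[expanded_idx] <- w[expanded_idx] * scenario$expansion_fold
        w[contracted_idx] <- w[contracted_idx] / scenario$contraction_fold
      }
      new_f <- rep(0, nrow(newc))
      if (!is.na(new_at_i) && ti >= new_at_i) {
        new_f <- newc$target_freq * scenario$new_decay^(ti - new_at_i)
      }
      w <- w / sum(w) * (1 - sum(new_f))
      probs <- c(w, new_f)
      expected[, ti] <- probs
      counts <- as.numeric(stats::rmultinom(1, scenario$library_sizes[ti], probs))
      keep <- counts > 0
      reps[[ti]] <- repertoire(
        tibble::tibble(nt_seq = all_clones$nt_seq[keep],
                       aa_seq = all_clones$aa_seq[keep],
                       count = counts[keep], productive = TRUE),
        sample_id = paste(scenario$patient_id, tp, sep = "_"),
        patient_id = scenario$patient_id, timepoint = tp)
    }
    colnames(expected) <- paste0("freq_", tps)
    truth_out <- dplyr::bind_cols(all_clones, tibble::as_tibble(expected))
    list(timecourse = timecourse(reps), truth = truth_out)
  })
}

#' Write a simulated time course as pipeline-ready fixtures
#'
#' Writes each sample in both dialects (immunoSEQ-style and AIRR), a sample
#' sheet pointing at the immunoSEQ files, and the ground-truth table, so a
#' simulated course can be fed to the pipeline exactly like real exports.
#'
#' @param tc a [timecourse()] (e.g. from [simulate_timecourse()]).
#' @param truth the matching ground-truth tibble (or `NULL` to skip).
#' @param dir output directory (created if needed).
#' @return named list of written paths, invisibly.
#' @export
export_fixtures <- function(tc, truth, dir) {
  stopifnot(is_timecourse(tc))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create fixture directory ", dir, call. = FALSE)
  files <- list()
  sheet <- list()
  for (rep in tc$repertoires) {
    is_path <- file.path(dir, paste0(rep$sample_id, "_immunoseq.tsv"))
    airr_path <- file.path(dir, paste0(rep$sample_id, "_airr.tsv"))
    write_repertoire(rep, is_path, dialect = "immunoseq")
    write_repertoire(rep, airr_path, dialect = "airr")
    files[[rep$sample_id]] <- c(immunoseq = is_path, airr = airr_path)
    sheet[[rep$sample_id]] <- tibble::tibble(
      sample_id = rep$sample_id, patient_id = rep$patient_id,
      timepoint = rep$timepoint, path = basename(is_path),
      dialect = "immunoseq")
  }
  sheet_path <- file.path(dir, "sample_sheet.tsv")
  readr::write_tsv(dplyr::bind_rows(sheet), sheet_path, progress = FALSE)
  files$sample_sheet <- sheet_path
  if (!is.null(truth)) {
    truth_path <- file.path(dir, "truth.tsv")
    readr::write_tsv(truth, truth_path, progress = FALSE)
    files$truth <- truth_path
  }
  invisible(files)
}
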