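# New-clone detection and classification among the most abundant follow-up
# clones, frequency-increase attribution, and longitudinal clone tracking.
#
# Each of the top-ranked follow-up nucleotide clones is assigned exactly one
# category relative to baseline, by precedence:
#   1. increased_nt     the identical nucleotide sequence was present at baseline
#   2. new_nt           new nucleotide sequence, amino-acid CDR3 present verbatim
#   3. new_similar_aa   new amino-acid CDR3 within Levenshtein distance 1 of a
#                       baseline amino-acid CDR3
#   4. new_aa           amino-acid CDR3 unrelated to baseline (distance >= 2)
# "New" is pure presence/absence of the nucleotide sequence at baseline, with
# no abundance floor; the library-size caveat (a rare pre-existing clone can
# look new at shallow baseline depth) is surfaced as a diagnostic.

CLONE_CATEGORIES <- c("increased_nt", "new_nt", "new_similar_aa", "new_aa")

#' Most abundant clones of a repertoire
#'
#' Returns the `n` highest-frequency clones at the nucleotide or amino-acid
#' level, with a deterministic tie-break: count descending, then sequence
#' lexicographically ascending.
#'
#' @param rep a productive-filtered [repertoire()].
#' @param n number of clones to return (all clones, ranked, if fewer exist).
#' @param level `"nt"` (default) or `"aa"`.
#' @return a tibble of the top clones with a `rank` column.
#' @export
top_clones <- function(rep, n = 100, level = c("nt", "aa")) {
  stopifnot(is_repertoire(rep))
  level <- match.arg(level)
  if (n <= 0) stop("n must be positive", call. = FALSE)
  tab <- if (level == "nt") {
    cl <- rep$clones[rep$clones$productive, c("nt_seq", "aa_seq", "count", "freq")]
    if (nrow(cl) == 0) stop("no productive clones", call. = FALSE)
    cl$freq <- cl$count / sum(cl$count)
    cl[order(-cl$count, cl$nt_seq), ]
  } else {
    aa <- aa_clonotypes(rep)
    aa[order(-aa$count, aa$aa_seq), c("aa_seq", "count", "freq")]
  }
  out <- utils::head(tab, n)
  out$rank <- seq_len(nrow(out))
  out
}

#' Classify the top follow-up clones against baseline
#'
#' Ranks the follow-up repertoire's nucleotide clones, keeps the top `n`, and
#' assigns each the first matching category: `increased_nt` (nucleotide
#' sequence detected at baseline), `new_nt` (new nucleotide sequence whose
#' amino-acid CDR3 exists verbatim at baseline), `new_similar_aa` (new
#' amino-acid CDR3 within Levenshtein distance 1 of a baseline CDR3) or
#' `new_aa` (unrelated to baseline). `delta_freq` is the follow-up frequency
#' minus the baseline frequency of the same nucleotide sequence (0 when
#' absent).
#'
#' The attribute `n_new_tcrs` counts the distinct new amino-acid CDR3s among
#' the classified clones (categories `new_aa` + `new_similar_aa`) — the
#' "number of new TCRs among the top n" summary.
#'
#' @param baseline,followup productive-filtered [repertoire()]s from the same
#'   patient.
#' @param n how many top follow-up clones to classify (default 100).
#' @return a tibble of class `clone_classification` with columns `nt_seq`,
#'   `aa_seq`, `followup_freq`, `baseline_freq`, `delta_freq`, `category`,
#'   and attributes `n_new_tcrs`, `baseline_sample`, `followup_sample`.
#' @export
classify_new_clones <- function(baseline, followup, n = 100) {
  stopifnot(is_repertoire(baseline), is_repertoire(followup))
  if (nrow(baseline$clones) == 0 || nrow(followup$clones) == 0) {
    stop("baseline and follow-up repertoires must be non-empty", call. = FALSE)
  }
  base_cl <- baseline$clones[baseline$clones$productive, , drop = FALSE]
  if (nrow(base_cl) == 0) stop("baseline has no productive clones", call. = FALSE)
  base_total <- sum(base_cl$count)
  base_freq <- stats::setNames(base_cl$count / base_total, base_cl$nt_seq)
  base_aa <- unique(base_cl$aa_seq)

  top <- top_clones(followup, n = n, level = "nt")
  in_base_nt <- top$nt_seq %in% names(base_freq)
  in_base_aa <- top$aa_seq %in% base_aa

  category <- rep(NA_character_, nrow(top))
  category[in_base_nt] <- "increased_nt"
  category[!in_base_nt & in_base_aa] <- "new_nt"
  todo <- is.na(category)
  if (any(todo)) {
    similar <- has_d1_neighbor(top$aa_seq[todo], base_aa)
    category[todo] <- ifelse(similar, "new_similar_aa", "new_aa")
  }
  baseline_freq <- unname(base_freq[top$nt_seq])
  baseline_freq[is.na(baseline_freq)] <- 0
  out <- tibble::tibble(
    nt_seq = top$nt_seq, aa_seq = top$aa_seq, rank = top$rank,
    followup_freq = top$freq, baseline_freq = baseline_freq,
    delta_freq = top$freq - baseline_freq,
    category = factor(category, levels = CLONE_CATEGORIES))
  new_aa_seqs <- unique(out$aa_seq[out$category %in% c("new_aa", "new_similar_aa")])
  structure(out,
            n_new_tcrs = length(new_aa_seqs),
            new_aa_seqs = new_aa_seqs,
            baseline_sample = baseline$sample_id,
            followup_sample = followup$sample_id,
            class = c("clone_classification", class(out)))
}

#' Attribute the total frequency increase to clone categories
#'
#' Sums, per category, the positive frequency gains of the classified top
#' clones: each clone contributes `max(delta_freq, 0)` (clones that shrank
#' contribute nothing — the quantity is the total *increase* in frequency).
#'
#' @param classifications a [classify_new_clones()] result.
#' @return a tibble with one row per category (`category`, `n_clones`,
#'   `total_increase`) plus attribute `grand_total`.
#' @export
attribute_frequency_increase <- function(classifications) {
  gains <- pmax(classifications$delta_freq %||% numeric(0), 0)
  cat <- factor(classifications$category, levels = CLONE_CATEGORIES)
  out <- tibble::tibble(
    category = factor(CLONE_CATEGORIES, levels = CLONE_CATEGORIES),
    n_clones = as.integer(table(cat)),
    total_increase = as.numeric(tapply(gains, cat, sum, default = 0)))
  structure(out, grand_total = sum(out$total_increase))
}

#' Select clones to track from an anchor timepoint
#'
#' Picks the `k` most abundant nucleotide clones of the anchor repertoire,
#' optionally restricted to clones absent from the time course's first
#' (baseline) repertoire — the "most abundant new clones". Uses
#' [top_clones()] ordering, so ties at the boundary break deterministically.
#'
#' @param tc a [timecourse()].
#' @param anchor anchor timepoint label (default `"cycle7"`).
#' @param k how many clones (default 7). Fewer are returned, with a warning,
#'   when not enough clones qualify.
#' @param new_only keep only clones undetected at the first timepoint.
#' @return a character vector of nucleotide sequences.
#' @export
select_tracking_set <- function(tc, anchor = "cycle7", k = 7, new_only = FALSE) {
  stopifnot(is_timecourse(tc), k >= 1)
  if (!anchor %in% tc$timepoints) {
    stop("anchor timepoint '", anchor, "' not present for patient ",
         tc$patient_id, call. = FALSE)
  }
  anchor_rep <- tc$repertoires[[anchor]]
  ranked <- top_clones(anchor_rep, n = nrow(anchor_rep$clones), level = "nt")
  if (new_only) {
    if (tc$timepoints[1] == anchor) {
      stop("new_only tracking needs a reference repertoire before the anchor",
           call. = FALSE)
    }
    base_nt <- tc$repertoires[[1]]$clones$nt_seq
    ranked <- ranked[!ranked$nt_seq %in% base_nt, , drop = FALSE]
    if (nrow(ranked) == 0) {
      warning("no new clones at anchor '", anchor, "' for patient ",
              tc$patient_id, call. = FALSE)
      return(character(0))
    }
  }
  if (nrow(ranked) < k) {
    warning("only ", nrow(ranked), " clone(s) available for tracking (k = ",
            k, ")", call. = FALSE)
  }
  utils::head(ranked$nt_seq, k)
}

#' Track clone frequencies across a time course
#'
#' Builds the clones-by-timepoints frequency matrix for a set of nucleotide
#' clone keys: frequency 0 where a clone is undetected. A clone that was
#' present and falls to 0 has disappeared; a fall of at least `drop_fold`
#' between consecutive timepoints is flagged as a dramatic decrease.
#'
#' @param tc a [timecourse()].
#' @param keys character vector of nucleotide sequences (e.g. from
#'   [select_tracking_set()]).
#' @param drop_fold fold-change defining a dramatic decrease (default 10).
#' @return a tibble of class `tracking_table`: `nt_seq`, `aa_seq`, one
#'   frequency column per timepoint, plus `disappeared` and
#'   `dramatic_decrease` flags (relative to each clone's running history).
#' @export
track_clones <- function(tc, keys, drop_fold = 10) {
  stopifnot(is_timecourse(tc))
  if (length(keys) == 0) stop("no clone keys to track", call. = FALSE)
  keys <- unique(as.character(keys))
  freq_at <- function(rep) {
    cl <- rep$clones[rep$clones$productive, , drop = FALSE]
    f <- stats::setNames(cl$count / sum(cl$count), cl$nt_seq)
    out <- unname(f[keys]); out[is.na(out)] <- 0; out
  }
  mat <- vapply(tc$repertoires, freq_at, numeric(length(keys)))
  mat <- matrix(mat, nrow = length(keys),
                dimnames = list(keys, tc$timepoints))
  aa_lookup <- do.call(rbind, lapply(tc$repertoires, function(r)
    r$clones[, c("nt_seq", "aa_seq")]))
  aa <- aa_lookup$aa_seq[match(keys, aa_lookup$nt_seq)]
  # flags over each clone's trajectory
  disappeared <- apply(mat, 1, function(f) any(f[-1] == 0 & cummax(f[-length(f)]) > 0))
  dramatic <- apply(mat, 1, function(f) {
    if (length(f) < 2) return(FALSE)
    prev <- f[-length(f)]; nxt <- f[-1]
    any(prev > 0 & nxt > 0 & prev / nxt >= drop_fold)
  })
  out <- tibble::as_tibble(cbind(
    tibble::tibble(nt_seq = keys, aa_seq = aa),
    tibble::as_tibble(mat)))
  out$disappeared <- disappeared
  out$dramatic_decrease <- dramatic
  structure(out, anchor = attr(keys, "anchor"),
            class = c("tracking_table", class(out)))
}

#' Cumulative frequency of the top clones per sample
#'
#' For each repertoire in a time course, the summed frequency of its own `k`
#' most abundant nucleotide clones — a simple measure of how clonal each
#' sample is.
#'
#' @param tc a [timecourse()].
#' @param k number of top clones (default 7).
#' @return a tibble with `timepoint`, `sample_id`, `cumulative_freq`.
#' @export
cumulative_top_frequency <- function(tc, k = 7) {
  stopifnot(is_timecourse(tc))
  rows <- lapply(tc$repertoires, function(rep) {
    tp <- top_clones(rep, n = k, level = "nt")
    tibble::tibble(timepoint = rep$timepoint, sample_id = rep$sample_id,
                   cumulative_freq = sum(tp$freq))
  })
  dplyr::bind_rows(rows)
}

#' New-clone counts among the top clones at every follow-up timepoint
#'
#' Convenience series used to compare a subject's follow-ups against its
#' first repertoire: for each later timepoint, the number of distinct new
#' amino-acid CDR3s among the `n` most abundant clones (categories `new_aa`
#' and `new_similar_aa`). This is the summary used to benchmark against
#' longitudinally sampled healthy-donor PBMC repertoires, whose top clones
#' are expected to stay largely stable over months.
#'
#' @param tc a [timecourse()] with at least two timepoints.
#' @param n how many top clones to consider (default 100).
#' @return a tibble with `patient_id`, `timepoint`, `n_new_tcrs` and the
#'   per-category clone counts.
#' @export
new_clone_count_series <- function(tc, n = 100) {
  stopifnot(is_timecourse(tc))
  if (length(tc$timepoints) < 2) {
    stop("need at least two timepoints to count new clones", call. = FALSE)
  }
  base_rep <- tc$repertoires[[1]]
  rows <- lapply(tc$timepoints[-1], function(tp) {
    cls <- classify_new_clones(base_rep, tc$repertoires[[tp]], n = n)
    counts <- table(cls$category)
    tibble::tibble(patient_id = tc$patient_id, timepoint = tp,
                   n_new_tcrs = attr(cls, "n_new_tcrs"),
                   n_increased_nt = as.integer(counts[["increased_nt"]]),
                   n_new_nt = as.integer(counts[["new_nt"]]),
                   n_new_similar_aa = as.integer(counts[["new_similar_aa"]]),
                   n_new_aa = as.integer(counts[["new_aa"]]))
  })
  dplyr::bind_rows(rows)
}
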