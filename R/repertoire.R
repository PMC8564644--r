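# Repertoire and time-course containers.
#
# A repertoire is one sample's set of unique nucleotide rearrangements
# (clones); the nucleotide CDR3 sequence is the primary clone key, and
# amino-acid clonotypes are derived by aggregating nucleotide variants that
# translate identically.

#' Construct a TCR repertoire
#'
#' Builds the package's central container: one row per unique nucleotide
#' CDR3 rearrangement with its amino-acid translation, template count and
#' productive status. Rows sharing a nucleotide sequence are merged by
#' summing counts. Clone frequencies are counts divided by the repertoire's
#' total template count.
#'
#' @param clones a data frame with columns `nt_seq` (nucleotide CDR3,
#'   A/C/G/T/N), `aa_seq` (amino-acid CDR3; empty string for out-of-frame
#'   rearrangements), `count` (non-negative template count) and `productive`
#'   (logical).
#' @param sample_id,patient_id,timepoint sample metadata. Metadata always
#'   comes from the caller (a sample sheet), never from file contents.
#' @return an object of class `tcr_repertoire`: a list with elements
#'   `sample_id`, `patient_id`, `timepoint`, `clones` (a tibble with an added
#'   `freq` column) and `total_count`.
#' @examples
#' rep <- repertoire(
#'   data.frame(nt_seq = c("TGTGCC", "TGTGCA"), aa_seq = c("CA", "CA"),
#'              count = c(5, 3), productive = TRUE),
#'   sample_id = "s1", patient_id = "p1", timepoint = "baseline")
#' rep$total_count
#' @export
repertoire <- function(clones, sample_id = "sample", patient_id = "patient",
                       timepoint = "baseline") {
  clones <- tibble::as_tibble(clones)
  required <- c("nt_seq", "aa_seq", "count", "productive")
  missing_cols <- setdiff(required, names(clones))
  if (length(missing_cols) > 0) {
    stop("clone table lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(clones) == 0) {
    stop("empty repertoire: no clone rows for sample '", sample_id, "'",
         call. = FALSE)
  }
  clones$nt_seq <- toupper(as.character(clones$nt_seq))
  clones$aa_seq <- toupper(trimws(ifelse(is.na(clones$aa_seq), "", as.character(clones$aa_seq))))
  if (any(!is.finite(clones$count)) || any(clones$count < 0)) {
    stop("clone counts must be non-negative finite numbers", call. = FALSE)
  }
  if (any(abs(clones$count - round(clones$count)) > 1e-8)) {
    stop("clone counts must be integers (template counts)", call. = FALSE)
  }
  clones$count <- as.numeric(round(clones$count))
  if (any(clones$nt_seq == "")) stop("nt_seq must be non-empty", call. = FALSE)
  bad_nt <- grepl("[^ACGTN]", clones$nt_seq)
  if (any(bad_nt)) {
    stop("nt_seq contains non-nucleotide characters in ",
         sum(bad_nt), " row(s)", call. = FALSE)
  }
  clones$productive <- as.logical(clones$productive)
  clones$productive[is.na(clones$productive)] <- FALSE
  # productive rearrangements must carry a usable amino-acid CDR3
  bad_aa <- clones$productive & (clones$aa_seq == "" | grepl("[*]", clones$aa_seq))
  if (any(bad_aa)) {
    stop(sum(bad_aa), " productive row(s) lack a valid amino-acid CDR3",
         call. = FALSE)
  }
  # ambiguous nucleotides retained but flagged, so totals are never silently altered
  clones$ambiguous <- grepl("N", clones$nt_seq, fixed = TRUE)

  # merge duplicate nucleotide rearrangements by summing counts
  if (anyDuplicated(clones$nt_seq)) {
    clones <- dplyr::summarise(
      dplyr::group_by(clones, .data$nt_seq),
      aa_seq = .data$aa_seq[1],
      count = sum(.data$count),
      productive = .data$productive[1],
      ambiguous = .data$ambiguous[1],
      .groups = "drop")
  }
  clones <- clones[clones$count > 0, , drop = FALSE]
  if (nrow(clones) == 0) {
    stop("empty repertoire: all clone counts are zero", call. = FALSE)
  }
  clones <- clones[order(-clones$count, clones$nt_seq), ]
  total <- sum(clones$count)
  clones$freq <- clones$count / total
  structure(
    list(sample_id = as.character(sample_id),
         patient_id = as.character(patient_id),
         timepoint = as.character(timepoint),
         clones = clones[, c("nt_seq", "aa_seq", "count", "freq",
                             "productive", "ambiguous")],
         total_count = total),
    class = "tcr_repertoire")
}

#' @export
print.tcr_repertoire <- function(x, ...) {
  cat(sprintf(
    "<tcr_repertoire> sample %s (patient %s, %s)\n  %d nucleotide clones, %s templates, %d productive\n",
    x$sample_id, x$patient_id, x$timepoint, nrow(x$clones),
    format(x$total_count, big.mark = ","), sum(x$clones$productive)))
  invisible(x)
}

is_repertoire <- function(x) inherits(x, "tcr_repertoire")

#' Keep only productive rearrangements
#'
#' Restricts a repertoire to in-frame, stop-codon-free clones and recomputes
#' the total count so that frequencies renormalize over the productive subset.
#' Productive clones are the substrate for all diversity and dynamics
#' analyses.
#'
#' @param rep a [repertoire()].
#' @return a `tcr_repertoire` containing only productive clones.
#' @export
filter_productive <- function(rep) {
  stopifnot(is_repertoire(rep))
  keep <- rep$clones[rep$clones$productive, , drop = FALSE]
  if (nrow(keep) == 0) {
    stop("no productive rearrangements in sample '", rep$sample_id, "'",
         call. = FALSE)
  }
  repertoire(keep[, c("nt_seq", "aa_seq", "count", "productive")],
             sample_id = rep$sample_id, patient_id = rep$patient_id,
             timepoint = rep$timepoint)
}

#' Aggregate a repertoire to amino-acid clonotypes
#'
#' Sums the counts of nucleotide variants that share an amino-acid CDR3
#' (convergent rearrangements). Diversity is computed on these amino-acid
#' clonotype frequencies.
#'
#' @param rep a [repertoire()].
#' @param productive_only drop non-productive clones first (default `TRUE`).
#' @return a tibble with columns `aa_seq`, `count`, `freq`, `n_nt_variants`,
#'   sorted by decreasing count (ties broken alphabetically).
#' @export
aa_clonotypes <- function(rep, productive_only = TRUE) {
  stopifnot(is_repertoire(rep))
  cl <- rep$clones
  if (productive_only) cl <- cl[cl$productive, , drop = FALSE]
  if (nrow(cl) == 0) stop("no clones to aggregate", call. = FALSE)
  agg <- dplyr::summarise(dplyr::group_by(cl, .data$aa_seq),
                          count = sum(.data$count),
                          n_nt_variants = dplyr::n(), .groups = "drop")
  agg <- agg[order(-agg$count, agg$aa_seq), ]
  agg$freq <- agg$count / sum(agg$count)
  agg[, c("aa_seq", "count", "freq", "n_nt_variants")]
}

# Count vector at the requested clonotype level (used by the diversity code).
clone_counts <- function(rep, level = c("aa", "nt"), productive_only = TRUE) {
  level <- match.arg(level)
  if (level == "aa") {
    aa_clonotypes(rep, productive_only = productive_only)$count
  } else {
    cl <- rep$clones
    if (productive_only) cl <- cl[cl$productive, , drop = FALSE]
    if (nrow(cl) == 0) stop("no clones at requested level", call. = FALSE)
    cl$count
  }
}

#' Assemble a per-patient time course
#'
#' Orders one patient's repertoires by timepoint (baseline, radiotherapy,
#' cycle7, cycle18, progression; custom labels follow in supplied order).
#'
#' @param reps a list of [repertoire()] objects from one patient.
#' @return an object of class `tcr_timecourse`: list with `patient_id`,
#'   `timepoints` and `repertoires` (named by timepoint).
#' @export
timecourse <- function(reps) {
  stopifnot(length(reps) >= 1, all(vapply(reps, is_repertoire, logical(1))))
  pids <- unique(vapply(reps, function(r) r$patient_id, character(1)))
  if (length(pids) != 1) {
    stop("all repertoires in a time course must share one patient_id; got: ",
         paste(pids, collapse = ", "), call. = FALSE)
  }
  tps <- vapply(reps, function(r) r$timepoint, character(1))
  if (anyDuplicated(tps)) {
    stop("duplicate timepoint(s) for patient ", pids, ": ",
         paste(unique(tps[duplicated(tps)]), collapse = ", "), call. = FALSE)
  }
  ord <- match(order_timepoints(tps), tps)
  reps <- reps[ord]
  names(reps) <- tps[ord]
  structure(list(patient_id = pids, timepoints = tps[ord], repertoires = reps),
            class = "tcr_timecourse")
}

#' @export
print.tcr_timecourse <- function(x, ...) {
  cat(sprintf("<tcr_timecourse> patient %s: %s\n", x$patient_id,
              paste(x$timepoints, collapse = " -> ")))
  invisible(x)
}

is_timecourse <- function(x) inherits(x, "tcr_timecourse")
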