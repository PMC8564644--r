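# Reading and writing rearrangement tables in the two dialects common in
# bulk TCR-beta sequencing: immunoSEQ-style exports and AIRR rearrangement
# TSV. Sample metadata (patient, timepoint) is supplied by the caller or a
# sample sheet, never inferred from file names or contents.

# Column synonyms accepted in immunoSEQ-style exports.
IMMUNOSEQ_SYNONYMS <- list(
  nt_seq = c("nucleotide", "rearrangement", "nucleotide_cdr3", "cdr3_rearrangement",
             "nt_seq", "nucleotideseq"),
  aa_seq = c("aminoacid", "amino_acid", "aa_seq", "cdr3_amino_acid", "aminoacidseq",
             "cdr3aa"),
  count = c("count_templates_reads", "templates", "count_templates", "count",
            "reads", "count_reads", "seq_reads", "templates_reads"),
  productive = c("sequencestatus", "sequence_status", "frame_type", "frametype",
                 "productive")
)

norm_header <- function(x) {
  x <- tolower(trimws(x))
  gsub("[^a-z0-9]+", "_", gsub("\\(|\\)", "", x))
}

match_column <- function(headers, synonyms) {
  hn <- norm_header(headers)
  sn <- norm_header(synonyms)
  hit <- which(hn %in% sn)
  if (length(hit) == 0) NA_integer_ else hit[1]
}

read_tsv_quiet <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE, na = character())
}

parse_count_column <- function(x, path) {
  x <- trimws(x)
  blank <- x == "" | is.na(x)
  suppressWarnings(num <- as.numeric(x))
  bad <- !blank & (is.na(num) | abs(num - round(num)) > 1e-8)
  if (any(bad)) {
    stop("non-integer count value(s) in ", basename(path), " at data line(s) ",
         paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
  }
  list(count = num, blank = blank)
}

#' Read an immunoSEQ-style rearrangement table
#'
#' Parses a tab-separated export with one row per unique nucleotide
#' rearrangement. Common column-name dialects are accepted: the nucleotide
#' column may be named `nucleotide` or `rearrangement`, the amino-acid column
#' `aminoAcid` or `amino_acid`, and the count column `count (templates/reads)`,
#' `templates`, `count` or `reads`. Template counts are preferred over read
#' counts when both are present. Rows sharing a nucleotide sequence are merged
#' by summing counts.
#'
#' Productive status is taken from a `sequenceStatus`/`frame_type` column when
#' present (`"In"` / `"In-frame"` is productive); if absent, rows with a
#' non-empty amino-acid CDR3 free of stop symbols (`*`) are treated as
#' productive.
#'
#' @param path path to the TSV file.
#' @inheritParams repertoire
#' @return a [repertoire()].
#' @export
read_immunoseq <- function(path, sample_id = basename(path),
                           patient_id = "patient", timepoint = "baseline") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- read_tsv_quiet(path)
  if (nrow(tab) == 0) {
    stop("empty repertoire: no data rows in ", basename(path), call. = FALSE)
  }
  idx <- lapply(IMMUNOSEQ_SYNONYMS, match_column, headers = names(tab))
  for (col in c("nt_seq", "aa_seq", "count")) {
    if (is.na(idx[[col]])) {
      stop("immunoSEQ format error in ", basename(path),
           ": no recognizable '", col, "' column (accepted: ",
           paste(IMMUNOSEQ_SYNONYMS[[col]], collapse = ", "), ")",
           call. = FALSE)
    }
  }
  cnt <- parse_count_column(tab[[idx$count]], path)
  if (any(cnt$blank)) {
    stop("blank count value(s) in ", basename(path), call. = FALSE)
  }
  aa <- toupper(trimws(tab[[idx$aa_seq]]))
  if (!is.na(idx$productive)) {
    status <- tolower(trimws(tab[[idx$productive]]))
    productive <- status %in% c("in", "in-frame", "inframe", "productive", "true", "t")
  } else {
    productive <- aa != "" & !grepl("[*]", aa)
  }
  repertoire(
    tibble::tibble(nt_seq = tab[[idx$nt_seq]], aa_seq = aa,
                   count = cnt$count, productive = productive),
    sample_id = sample_id, patient_id = patient_id, timepoint = timepoint)
}

#' Read an AIRR rearrangement table
#'
#' Parses a tab-separated file following the AIRR Community rearrangement
#' schema: columns `junction` (nucleotide CDR3), `junction_aa`,
#' `duplicate_count` and `productive`. A blank `duplicate_count` (nullable in
#' the schema) is treated as count 1 with a warning. `productive` values
#' `T`/`TRUE`/`true` (and `F`/`FALSE`/`false`) map to logical.
#'
#' @inheritParams read_immunoseq
#' @return a [repertoire()].
#' @export
read_airr <- function(path, sample_id = basename(path),
                      patient_id = "patient", timepoint = "baseline") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- read_tsv_quiet(path)
  if (nrow(tab) == 0) {
    stop("empty repertoire: no data rows in ", basename(path), call. = FALSE)
  }
  required <- c("junction", "junction_aa", "duplicate_count", "productive")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop("AIRR format error in ", basename(path), ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  cnt <- parse_count_column(tab$duplicate_count, path)
  if (any(cnt$blank)) {
    warning(sum(cnt$blank), " row(s) with blank duplicate_count in ",
            basename(path), " treated as count 1", call. = FALSE)
    cnt$count[cnt$blank] <- 1
  }
  productive <- tolower(trimws(tab$productive)) %in% c("t", "true")
  repertoire(
    tibble::tibble(nt_seq = tab$junction, aa_seq = toupper(trimws(tab$junction_aa)),
                   count = cnt$count, productive = productive),
    sample_id = sample_id, patient_id = patient_id, timepoint = timepoint)
}

#' Write a repertoire to disk
#'
#' Writes a repertoire as a TSV in either dialect. Reading the file back with
#' the matching reader reproduces `nt_seq`, `aa_seq` and `count` exactly.
#'
#' @param rep a [repertoire()].
#' @param path output file path.
#' @param dialect `"immunoseq"` or `"airr"`.
#' @return `path`, invisibly.
#' @export
write_repertoire <- function(rep, path, dialect = c("immunoseq", "airr")) {
  stopifnot(is_repertoire(rep))
  dialect <- match.arg(dialect)
  if (nrow(rep$clones) == 0) stop("refusing to write an empty repertoire", call. = FALSE)
  cl <- rep$clones
  out <- switch(dialect,
    immunoseq = tibble::tibble(
      nucleotide = cl$nt_seq,
      aminoAcid = cl$aa_seq,
      `count (templates/reads)` = cl$count,
      sequenceStatus = ifelse(cl$productive, "In", "Out")),
    airr = tibble::tibble(
      junction = cl$nt_seq,
      junction_aa = cl$aa_seq,
      duplicate_count = cl$count,
      productive = ifelse(cl$productive, "T", "F")))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' A sample sheet maps files to metadata: tab-separated with columns
#' `sample_id`, `patient_id`, `timepoint`, `path` and optionally `dialect`
#' (`immunoseq`/`airr`; default immunoseq). Relative paths are resolved
#' against the sheet's directory.
#'
#' @param path path to the sample sheet TSV.
#' @return a tibble, one row per sample.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path, call. = FALSE)
  sheet <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  required <- c("sample_id", "patient_id", "timepoint", "path")
  missing_cols <- setdiff(required, names(sheet))
  if (length(missing_cols) > 0) {
    stop("sample sheet missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(sheet$sample_id)) {
    stop("duplicate sample_id in sample sheet", call. = FALSE)
  }
  if (!"dialect" %in% names(sheet)) sheet$dialect <- "immunoseq"
  sheet$dialect[is.na(sheet$dialect) | sheet$dialect == ""] <- "immunoseq"
  rel <- !grepl("^(/|[A-Za-z]:)", sheet$path)
  sheet$path[rel] <- file.path(dirname(path), sheet$path[rel])
  sheet
}

#' Load per-patient time courses from a sample sheet
#'
#' Reads every sample listed in a sheet (see [read_sample_sheet()]) and
#' groups the repertoires into one [timecourse()] per patient.
#'
#' @param sheet a sample-sheet tibble or a path to one.
#' @param productive_only restrict each repertoire to productive
#'   rearrangements (default `TRUE`, the analysis substrate).
#' @return a named list of `tcr_timecourse` objects, one per patient.
#' @export
load_timecourses <- function(sheet, productive_only = TRUE) {
  if (is.character(sheet)) sheet <- read_sample_sheet(sheet)
  reps <- lapply(seq_len(nrow(sheet)), function(i) {
    reader <- switch(sheet$dialect[i], immunoseq = read_immunoseq,
                     airr = read_airr,
                     stop("unknown dialect: ", sheet$dialect[i], call. = FALSE))
    r <- reader(sheet$path[i], sample_id = sheet$sample_id[i],
                patient_id = sheet$patient_id[i], timepoint = sheet$timepoint[i])
    if (productive_only) r <- filter_productive(r)
    r
  })
  by_patient <- split(reps, vapply(reps, function(r) r$patient_id, character(1)))
  lapply(by_patient, timecourse)
}
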