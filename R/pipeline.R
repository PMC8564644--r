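# Pipeline driver: from a sample sheet to the full set of per-patient output
# tables (diversity profiles, Shannon change calls, new-clone classification
# and attribution, tracking matrices, cumulative top-clone frequencies,
# similarity-network exports), with one master seed and a run manifest.

#' Configure a repertoire-analysis pipeline run
#'
#' Collects every tunable parameter of [run_pipeline()]. The defaults are the
#' analysis settings used throughout the package: 70 000-read subsampling
#' with 500 permutations for diversity, a 1% Shannon-change threshold, the
#' top 100 clones for new-clone classification, a 0.001 network frequency
#' threshold and 7 tracked clones anchored at cycle 7.
#'
#' @param sample_sheet path to a sample sheet (see [read_sample_sheet()]).
#' @param output_dir directory for the report tables (created if needed).
#' @param depth subsampling depth in reads.
#' @param permutations subsampling repetitions averaged.
#' @param top_n number of top follow-up clones classified.
#' @param change_threshold relative Shannon-deviation threshold for
#'   increased/decreased calls.
#' @param network_threshold minimum clonotype frequency for network nodes.
#' @param tracking_k clones tracked per selection rule.
#' @param anchor anchor timepoint for tracking-set selection.
#' @param alphas Rényi order grid.
#' @param seed master seed for all subsampling streams.
#' @param on_short_library policy when a library is smaller than `depth`:
#'   `"full"` (compute on the full sample, with a warning) or `"error"`.
#' @param productive_only restrict samples to productive rearrangements.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(sample_sheet, output_dir,
                            depth = 70000, permutations = 500,
                            top_n = 100, change_threshold = 0.01,
                            network_threshold = 0.001, tracking_k = 7,
                            anchor = "cycle7", alphas = renyi_alphas(),
                            seed = 1, on_short_library = c("full", "error"),
                            productive_only = TRUE) {
  stopifnot(depth > 0, permutations > 0, top_n > 0, change_threshold > 0,
            network_threshold > 0, tracking_k > 0)
  structure(
    list(sample_sheet = sample_sheet, output_dir = output_dir,
         depth = depth, permutations = permutations, top_n = top_n,
         change_threshold = change_threshold,
         network_threshold = network_threshold, tracking_k = tracking_k,
         anchor = anchor, alphas = alphas, seed = seed,
         on_short_library = match.arg(on_short_library),
         productive_only = productive_only),
    class = "pipeline_config")
}

#' Run the full repertoire analysis pipeline
#'
#' For every patient in the sample sheet: depth-normalized Rényi profiles
#' per sample; a Shannon time series with increased/decreased/unchanged
#' calls against the patient's first available timepoint (when baseline is
#' missing, the earliest sample is the reference); new-clone classification
#' of the top clones and per-category frequency-increase attribution at
#' every follow-up timepoint; tracking matrices for the most abundant and
#' most abundant *new* clones at the anchor timepoint; cumulative top-clone
#' frequencies per sample; and per-sample similarity-network edge/node
#' tables. A `manifest.json` records the configuration, seed, package
#' version and per-sample read counts so every output is traceable.
#'
#' Per-patient failures are caught, logged and skipped; the returned report
#' records them, and `exit_code` is 0 only for a fully clean run.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the output `tables` (tibbles), `failures`
#'   (named character vector of error messages) and `exit_code`
#'   (0 ok, 2 any per-patient failure).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  net_dir <- file.path(config$output_dir, "networks")
  dir.create(net_dir, showWarnings = FALSE)
  sheet <- read_sample_sheet(config$sample_sheet)
  failures <- character(0)

  # load samples individually so one unreadable file cannot abort the run
  reps <- list()
  for (i in seq_len(nrow(sheet))) {
    r <- tryCatch(
      load_timecourses(sheet[i, , drop = FALSE],
                       productive_only = config$productive_only)[[1]]$repertoires[[1]],
      error = function(e) e)
    if (inherits(r, "error")) {
      message("pipeline: sample ", sheet$sample_id[i], " failed: ",
              conditionMessage(r))
      failures[sheet$sample_id[i]] <- conditionMessage(r)
    } else {
      reps[[sheet$sample_id[i]]] <- r
    }
  }
  if (length(reps) == 0) stop("no sample in the sheet could be loaded", call. = FALSE)
  courses <- lapply(split(reps, vapply(reps, function(r) r$patient_id,
                                       character(1))), timecourse)

  profiles <- list(); changes <- list(); class_rows <- list()
  attributions <- list(); new_counts <- list(); tracking_paths <- character(0)
  cumtop <- list()
  on_short <- config$on_short_library

  for (pid in names(courses)) {
    tc <- courses[[pid]]
    res <- tryCatch({
      # --- diversity: subsampled profiles + Shannon change calls ---
      prof <- lapply(tc$repertoires, function(rep) {
        p <- subsampled_renyi(rep, depth = config$depth,
                              permutations = config$permutations,
                              seed = config$seed, alphas = config$alphas,
                              on_short = on_short)
        tibble::tibble(patient_id = pid, sample_id = rep$sample_id,
                       timepoint = rep$timepoint, alpha = p$alpha, H = p$H,
                       depth = as.character(attr(p, "depth")),
                       permutations = attr(p, "permutations"))
      })
      prof <- dplyr::bind_rows(prof)
      shan <- prof[prof$alpha == 1, ]
      ref_H <- shan$H[1]  # first (earliest) timepoint is the reference
      ch <- lapply(seq_len(nrow(shan)), function(i) {
        dc <- classify_diversity_change(ref_H, shan$H[i],
                                        threshold = config$change_threshold)
        tibble::tibble(patient_id = pid, sample_id = shan$sample_id[i],
                       timepoint = shan$timepoint[i],
                       baseline_H = dc$baseline_H, H = dc$current_H,
                       relative_deviation = dc$relative_deviation,
                       call = as.character(dc$call))
      })
      ch <- dplyr::bind_rows(ch)

      # --- dynamics: new-clone classification at every follow-up ---
      cls_list <- list(); attr_list <- list(); cnt_list <- list()
      if (length(tc$timepoints) >= 2) {
        base_rep <- tc$repertoires[[1]]
        for (tp in tc$timepoints[-1]) {
          cls <- classify_new_clones(base_rep, tc$repertoires[[tp]],
                                     n = config$top_n)
          cls_list[[tp]] <- dplyr::bind_cols(
            tibble::tibble(patient_id = pid, timepoint = tp),
            tibble::as_tibble(cls))
          att <- attribute_frequency_increase(cls)
          attr_list[[tp]] <- dplyr::bind_cols(
            tibble::tibble(patient_id = pid, timepoint = tp),
            tibble::as_tibble(att))
          cnt_list[[tp]] <- tibble::tibble(
            patient_id = pid, timepoint = tp,
            n_new_tcrs = attr(cls, "n_new_tcrs"),
            total_increase = attr(att, "grand_total"))
        }
      }

      # --- tracking at the anchor timepoint ---
      track_files <- character(0)
      if (config$anchor %in% tc$timepoints &&
          match(config$anchor, tc$timepoints) > 1) {
        for (rule in c("all", "new")) {
          keys <- select_tracking_set(tc, anchor = config$anchor,
                                      k = config$tracking_k,
                                      new_only = rule == "new")
          if (length(keys) > 0) {
            tt <- track_clones(tc, keys)
            path <- file.path(config$output_dir,
                              sprintf("tracking_%s_%s.tsv", pid, rule))
            readr::write_tsv(tibble::as_tibble(tt), path, progress = FALSE)
            track_files <- c(track_files, path)
          }
        }
      }

      # --- similarity networks per sample ---
      for (rep in tc$repertoires) {
        new_aa <- character(0)
        if (rep$timepoint %in% names(cls_list)) {
          cl <- cls_list[[rep$timepoint]]
          new_aa <- cl$aa_seq[cl$category %in% c("new_aa", "new_similar_aa")]
        }
        net <- suppressWarnings(
          build_network(rep, freq_threshold = config$network_threshold,
                        new_aa = new_aa))
        write_network(net, file.path(net_dir, rep$sample_id))
      }

      list(prof = prof, ch = ch,
           cls = dplyr::bind_rows(cls_list), att = dplyr::bind_rows(attr_list),
           cnt = dplyr::bind_rows(cnt_list),
           cum = dplyr::bind_cols(tibble::tibble(patient_id = pid),
                                  cumulative_top_frequency(tc, k = config$tracking_k)),
           track = track_files)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      message("pipeline: patient ", pid, " failed: ", conditionMessage(res))
      failures[pid] <- conditionMessage(res)
      next
    }
    profiles[[pid]] <- res$prof; changes[[pid]] <- res$ch
    class_rows[[pid]] <- res$cls; attributions[[pid]] <- res$att
    new_counts[[pid]] <- res$cnt; cumtop[[pid]] <- res$cum
    tracking_paths <- c(tracking_paths, res$track)
  }

  tables <- list(
    renyi_profiles = dplyr::bind_rows(profiles),
    shannon_changes = dplyr::bind_rows(changes),
    clone_classifications = dplyr::bind_rows(class_rows),
    category_attribution = dplyr::bind_rows(attributions),
    new_clone_counts = dplyr::bind_rows(new_counts),
    cumulative_top_clones = dplyr::bind_rows(cumtop))
  for (nm in names(tables)) {
    readr::write_tsv(tables[[nm]], file.path(config$output_dir,
                                             paste0(nm, ".tsv")),
                     progress = FALSE)
  }
  manifest <- list(
    package = "tcrdyn",
    version = as.character(utils::packageVersion("tcrdyn")),
    config = config[setdiff(names(config), character(0))],
    seed = config$seed,
    samples = stats::setNames(
      lapply(unlist(lapply(courses, function(tc) tc$repertoires),
                    recursive = FALSE),
             function(r) list(sample_id = r$sample_id, patient_id = r$patient_id,
                              timepoint = r$timepoint,
                              total_count = r$total_count,
                              n_clones = nrow(r$clones))),
      NULL),
    failures = as.list(failures))
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(list(tables = tables, failures = failures,
                 tracking_files = tracking_paths,
                 output_dir = config$output_dir,
                 exit_code = if (length(failures) > 0) 2L else 0L))
}
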