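#' Assemble a pipeline configuration
#'
#' Gathers every analysis constant behind one named, defaulted parameter
#' list so sensitivity analyses are one-line changes: ROI retention floors
#' (100 voxels, 25% mask overlap), the motion-exclusion threshold (3 of 6
#' epoch TRs), the FDR level (0.05), the degrees-of-freedom method, the
#' pattern currency, and the high-pass cutoff (100 s). A configuration can
#' also be read from a YAML file; explicit arguments override file values.
#'
#' @param file Optional YAML file with any of these fields (a `synthetic`
#'   block is passed to [synth_config()]).
#' @param synthetic A [synth_config()] (or argument list) for simulated
#'   input; alternatively set `input_dir` to a study written by
#'   [write_study()].
#' @param input_dir Directory with a previously written study.
#' @param out_dir Optional output directory for persisted intermediates.
#' @param min_voxels,min_overlap ROI retention rule (see [select_rois()]).
#' @param motion_threshold Flagged TRs per focal epoch triggering exclusion.
#' @param fdr_q FDR level.
#' @param df_method `"satterthwaite"` or `"kenward-roger"`.
#' @param pattern_stat `"t"` or `"beta"`.
#' @param highpass_s High-pass cutoff (seconds).
#' @param three_way Keep the three-way interaction term.
#' @return A `cftnps_config` list.
#' @export
pipeline_config <- function(file = NULL, synthetic = synth_config(),
                            input_dir = NULL, out_dir = NULL,
                            min_voxels = 100L, min_overlap = 0.25,
                            motion_threshold = 3L, fdr_q = 0.05,
                            df_method = "satterthwaite", pattern_stat = "t",
                            highpass_s = 100, three_way = TRUE) {
  cfg <- list(
    synthetic = synthetic, input_dir = input_dir, out_dir = out_dir,
    min_voxels = min_voxels, min_overlap = min_overlap,
    motion_threshold = motion_threshold, fdr_q = fdr_q,
    df_method = df_method, pattern_stat = pattern_stat,
    highpass_s = highpass_s, three_way = three_way
  )
  if (!is.null(file)) {
    y <- yaml::read_yaml(file)
    if (!is.null(y$synthetic)) {
      cfg$synthetic <- do.call(synth_config, y$synthetic)
      y$synthetic <- NULL
    }
    for (nm in names(y)) cfg[[nm]] <- y[[nm]]
  }
  if (is.list(cfg$synthetic) && !inherits(cfg$synthetic, "cftnps_synth_config")) {
    cfg$synthetic <- do.call(synth_config, cfg$synthetic)
  }
  class(cfg) <- "cftnps_config"
  cfg
}

#' Run the full pattern-similarity pipeline
#'
#' Executes every stage in order -- simulate (or load), select ROIs,
#' extract single-trial FIR/LSS patterns with motion exclusion, compute
#' and residualize the similarity indices, fit the per-ROI mixed models
#' with FDR correction -- and returns all intermediates together with an
#' accounting report in which every dropped record is attributed to a
#' named rule (motion exclusion, undefined correlation, empty cross-run
#' comparison set).
#'
#' @param config A [pipeline_config()].
#' @return List: `study`, `roi_table`, `patterns`, `index_table` (adjusted
#'   shift + CFT-CFT records), `sweep` (see [run_roi_sweep()]), `report`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "cftnps_config"))
  study <- if (!is.null(config$input_dir)) read_study(config$input_dir)
           else generate_study(config$synthetic)

  roi_table <- select_rois(study$atlas, study$omnibus_mask,
                           min_voxels = config$min_voxels,
                           min_overlap = config$min_overlap)
  retained <- roi_table$label[roi_table$retained]

  ecft <- study$events[study$events$condition %in% c("upward", "downward"), ]
  n_trials_total <- nrow(study$events)
  n_ecft <- nrow(ecft)

  empty_report <- list(
    n_trials_total = n_trials_total, n_ecft_trials = n_ecft,
    n_rois = nrow(roi_table), n_rois_retained = length(retained),
    n_motion_excluded = 0L, n_shift_undefined = 0L, n_cc_unavailable = 0L,
    n_models_attempted = 0L, n_models_converged = 0L, accounting_ok = TRUE
  )
  if (length(retained) == 0L) {
    out <- list(study = study, roi_table = roi_table, patterns = NULL,
                index_table = NULL,
                sweep = list(results = NULL, slopes = NULL, fits = list(),
                             failures = NULL),
                report = empty_report, config = config)
    persist_pipeline(out, config$out_dir)
    return(out)
  }

  patterns <- extract_study_patterns(
    study, retained, pattern_stat = config$pattern_stat,
    highpass_s = config$highpass_s, motion_threshold = config$motion_threshold
  )
  excl_trials <- unique(patterns[patterns$excluded,
                                 c("subject_id", "run_id", "memory_id")])
  raw <- compute_index_table(patterns, study$covariates)
  shift_raw <- raw[raw$index_kind == "recall_cft_shift_raw", ]
  cc <- raw[raw$index_kind == "cft_cft_similarity", ]
  adjusted <- residualize_shift(shift_raw)
  index_table <- rbind(adjusted, cc)

  sweep <- run_roi_sweep(index_table, roi_labels = retained,
                         q = config$fdr_q, df_method = config$df_method,
                         three_way = config$three_way)

  n_analyzed_trials <- nrow(unique(
    raw[!is.na(raw$value), c("subject_id", "run_id", "memory_id")]))
  report <- list(
    n_trials_total = n_trials_total,
    n_ecft_trials = n_ecft,
    n_rois = nrow(roi_table),
    n_rois_retained = length(retained),
    n_motion_excluded = nrow(excl_trials),
    n_shift_undefined = sum(is.na(shift_raw$value)),
    n_cc_unavailable = sum(is.na(cc$value)),
    n_models_attempted = length(sweep$fits) +
      if (is.null(sweep$failures)) 0L else nrow(sweep$failures),
    n_models_converged = sum(vapply(sweep$fits, `[[`, logical(1), "converged")),
    # every eCFT trial is analyzed unless motion-excluded (index-level NA
    # records are per-ROI drops, tallied separately above)
    accounting_ok = (nrow(unique(
      patterns[!patterns$excluded, c("subject_id", "run_id", "memory_id")])) +
        nrow(excl_trials)) == n_ecft
  )
  out <- list(study = study, roi_table = roi_table, patterns = patterns,
              index_table = index_table, sweep = sweep, report = report,
              config = config)
  persist_pipeline(out, config$out_dir)
  out
}

# write tabular intermediates + report if an output directory is configured
persist_pipeline <- function(out, out_dir) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(out$roi_table, file.path(out_dir, "roi_table.csv"),
                   row.names = FALSE)
  if (!is.null(out$index_table)) {
    utils::write.csv(out$index_table, file.path(out_dir, "index_table.csv"),
                     row.names = FALSE)
  }
  if (!is.null(out$sweep$results)) {
    utils::write.csv(out$sweep$results, file.path(out_dir, "lmem_results.csv"),
                     row.names = FALSE)
    utils::write.csv(out$sweep$slopes, file.path(out_dir, "simple_slopes.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(out$report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}
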