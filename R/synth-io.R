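#' Write a synthetic study to disk in standard neuroimaging formats
#'
#' Serializes a study from [generate_study()]: 4D BOLD NIfTI per run,
#' BIDS-style events TSV (onset, duration, trial_type, memory_id, jitter_s,
#' prev_condition), per-TR confounds TSV with the motion-outlier flag,
#' atlas and omnibus-mask NIfTI volumes, a covariates CSV, the synthetic
#' ground-truth trial table, and a JSON manifest tying it together. Volumes
#' are written as float64 so a round-trip read reproduces arrays exactly.
#'
#' @param study Study list from [generate_study()].
#' @param out_dir Output directory (created if absent).
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
write_study <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("write_study: cannot create ", out_dir)
  dims <- dim(study$atlas)
  RNifti::writeNifti(array(as.double(study$atlas), dims),
                     file.path(out_dir, "atlas.nii.gz"), datatype = "double")
  RNifti::writeNifti(array(as.double(study$omnibus_mask), dims),
                     file.path(out_dir, "omnibus_mask.nii.gz"), datatype = "double")
  utils::write.csv(study$covariates, file.path(out_dir, "covariates.csv"),
                   row.names = FALSE)
  utils::write.csv(study$truth$trials, file.path(out_dir, "truth_trials.csv"),
                   row.names = FALSE)

  run_entries <- lapply(study$runs, function(run) {
    stub <- paste0(run$subject_id, "_", run$run_id)
    bold_file <- paste0(stub, "_bold.nii.gz")
    n_tr <- ncol(run$signal)
    RNifti::writeNifti(
      array(run$signal, c(dims, n_tr)),
      file.path(out_dir, bold_file), datatype = "double"
    )
    conf <- cbind(run$confounds, motion_outlier = as.integer(run$outlier_flags))
    conf_file <- paste0(stub, "_confounds.tsv")
    utils::write.table(conf, file.path(out_dir, conf_file), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    ev <- study$events[study$events$subject_id == run$subject_id &
                         study$events$run_id == run$run_id, , drop = FALSE]
    long <- rbind(
      data.frame(onset = ev$recall_onset, duration = 12, trial_type = "recall",
                 memory_id = ev$memory_id, jitter_s = ev$jitter_s,
                 prev_condition = ev$prev_condition),
      {
        e2 <- ev[ev$condition != "none", , drop = FALSE]
        data.frame(onset = e2$cft_onset, duration = 12,
                   trial_type = paste0("cft_", e2$condition),
                   memory_id = e2$memory_id, jitter_s = e2$jitter_s,
                   prev_condition = e2$prev_condition)
      },
      data.frame(onset = run$filler_events$onset,
                 duration = run$filler_events$duration,
                 trial_type = "oddeven", memory_id = NA, jitter_s = NA,
                 prev_condition = NA),
      data.frame(onset = run$button_presses, duration = 0.1,
                 trial_type = "button_press", memory_id = NA, jitter_s = NA,
                 prev_condition = NA)
    )
    long <- long[order(long$onset), ]
    ev_file <- paste0(stub, "_events.tsv")
    utils::write.table(long, file.path(out_dir, ev_file), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    list(subject_id = run$subject_id, run_id = run$run_id,
         tr_seconds = run$tr_seconds, n_tr = n_tr,
         bold = bold_file, events = ev_file, confounds = conf_file)
  })

  manifest <- list(
    package = "cftnps",
    config = unclass(study$config),
    volume_dim = dims,
    atlas = "atlas.nii.gz", omnibus_mask = "omnibus_mask.nii.gz",
    covariates = "covariates.csv", truth_trials = "truth_trials.csv",
    runs = run_entries
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a study previously written by [write_study()]
#'
#' @param dir Directory containing `manifest.json` and the study files.
#' @return A study list with the same structure as [generate_study()]
#'   output (`truth` restricted to the trial table).
#' @export
read_study <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  atlas <- array(as.integer(RNifti::readNifti(file.path(dir, mf$atlas))),
                 dim = mf$volume_dim)
  mask <- array(as.integer(RNifti::readNifti(file.path(dir, mf$omnibus_mask))),
                dim = mf$volume_dim)
  covariates <- utils::read.csv(file.path(dir, mf$covariates),
                                stringsAsFactors = FALSE)
  truth <- utils::read.csv(file.path(dir, mf$truth_trials), stringsAsFactors = FALSE)
  n_vox <- prod(mf$volume_dim)
  runs <- list()
  events_acc <- list()
  for (i in seq_len(nrow(mf$runs))) {
    entry <- mf$runs[i, ]
    bold <- RNifti::readNifti(file.path(dir, entry$bold))
    signal <- matrix(as.vector(bold), n_vox, entry$n_tr)
    conf <- utils::read.delim(file.path(dir, entry$confounds))
    long <- utils::read.delim(file.path(dir, entry$events),
                              stringsAsFactors = FALSE)
    rec <- long[long$trial_type == "recall", , drop = FALSE]
    rec <- rec[order(rec$onset), ]
    cft <- long[grepl("^cft_", long$trial_type), , drop = FALSE]
    cond <- sub("^cft_", "", cft$trial_type[match(rec$memory_id, cft$memory_id)])
    cond[is.na(cond)] <- "none"
    ev <- data.frame(
      subject_id = entry$subject_id, run_id = entry$run_id,
      trial_index = seq_len(nrow(rec)), memory_id = rec$memory_id,
      condition = cond,
      recall_onset = rec$onset,
      cft_onset = cft$onset[match(rec$memory_id, cft$memory_id)],
      jitter_s = rec$jitter_s, prev_condition = rec$prev_condition,
      stringsAsFactors = FALSE
    )
    events_acc[[i]] <- ev
    runs[[i]] <- list(
      subject_id = entry$subject_id, run_id = entry$run_id,
      tr_seconds = entry$tr_seconds, signal = signal,
      confounds = conf[, setdiff(names(conf), "motion_outlier")],
      outlier_flags = conf$motion_outlier == 1,
      filler_events = {
        f <- long[long$trial_type == "oddeven", c("onset", "duration")]
        rownames(f) <- NULL
        f
      },
      button_presses = long$onset[long$trial_type == "button_press"]
    )
  }
  cfg <- mf$config
  cfg$jitter_choices <- as.numeric(cfg$jitter_choices)
  cfg <- do.call(synth_config, cfg)
  list(runs = runs, events = do.call(rbind, events_acc),
       covariates = covariates, atlas = atlas, omnibus_mask = mask,
       truth = list(trials = truth), config = cfg)
}
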