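#' Compute trial-level similarity index records from window patterns
#'
#' Turns the per-trial window-pattern table from
#' [extract_study_patterns()] into one index record per eCFT trial x ROI x
#' index kind: the raw Recall-CFT similarity shift (difference of Fisher-z
#' correlations of the recall 4-8 s pattern with the late vs. early CFT
#' window) and the CFT-CFT similarity (mean Fisher-z correlation of the
#' trial's CFT 4-8 s pattern with every same-condition CFT pattern from
#' other runs). Records whose correlations are undefined (zero-variance
#' pattern) or whose cross-run comparison set is empty carry `NA` values
#' and are excluded downstream with an accounting entry, not imputed.
#'
#' @param patterns Window-pattern table from [extract_study_patterns()].
#' @param covariates Covariate table (`subject_id`, `stai_y2`, `memory_id`,
#'   `arousal`).
#' @return Data frame of index records: identifiers, nuisance covariates
#'   (`jitter_s`, `prev_condition`), `anxiety`, `arousal`, `index_kind`,
#'   `value`, and `m` (cross-run pair count, CFT-CFT records only).
#' @export
compute_index_table <- function(patterns, covariates) {
  pat <- patterns[!patterns$excluded, , drop = FALSE]
  out <- list()
  for (sid in unique(pat$subject_id)) {
    for (roi in unique(pat$roi_label)) {
      sub <- pat[pat$subject_id == sid & pat$roi_label == roi, , drop = FALSE]
      trials <- unique(sub[, c("run_id", "memory_id", "condition",
                               "jitter_s", "prev_condition")])
      n_t <- nrow(trials)
      if (n_t == 0L) next
      grab <- function(epoch, window) {
        idx <- match(
          paste(trials$run_id, trials$memory_id),
          paste(sub$run_id, sub$memory_id)[sub$epoch == epoch & sub$window == window]
        )
        cols <- sub$pattern[sub$epoch == epoch & sub$window == window][idx]
        do.call(cbind, cols)
      }
      m_rec <- grab("recall", "w4_8")
      m_c04 <- grab("cft", "w0_4")
      m_c48 <- grab("cft", "w4_8")
      r_early <- suppressWarnings(diag(stats::cor(m_rec, m_c04)))
      r_late <- suppressWarnings(diag(stats::cor(m_rec, m_c48)))
      shift <- fisher_z(r_late) - fisher_z(r_early)

      cz <- fisher_z(suppressWarnings(stats::cor(m_c48)))
      same_cond <- outer(trials$condition, trials$condition, "==")
      diff_run <- outer(trials$run_id, trials$run_id, "!=")
      use <- same_cond & diff_run & !is.na(cz)
      diag(use) <- FALSE
      m_count <- rowSums(use)
      cc <- ifelse(m_count > 0, rowSums(ifelse(use, cz, 0)) / m_count, NA_real_)

      base <- data.frame(
        subject_id = sid, roi_label = roi,
        run_id = trials$run_id, memory_id = trials$memory_id,
        condition = trials$condition, jitter_s = trials$jitter_s,
        prev_condition = trials$prev_condition, stringsAsFactors = FALSE
      )
      out[[length(out) + 1L]] <- rbind(
        cbind(base, index_kind = "recall_cft_shift_raw", value = shift,
              m = NA_integer_),
        cbind(base, index_kind = "cft_cft_similarity", value = cc,
              m = m_count)
      )
    }
  }
  rec <- do.call(rbind, out)
  if (is.null(rec)) return(NULL)
  rownames(rec) <- NULL
  subj_anx <- unique(covariates[, c("subject_id", "stai_y2")])
  rec$anxiety <- subj_anx$stai_y2[match(rec$subject_id, subj_anx$subject_id)]
  rec$arousal <- covariates$arousal[match(
    paste(rec$subject_id, rec$memory_id),
    paste(covariates$subject_id, covariates$memory_id)
  )]
  rec
}
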