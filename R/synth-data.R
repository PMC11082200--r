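#' Configuration for a synthetic eCFT pattern-similarity study
#'
#' Defines the study conditions the generator emulates: per subject, three
#' fMRI runs of 45 trials total (15 per condition: upward eCFT, downward
#' eCFT, No eCFT), each trial a 12-s autobiographical recall epoch followed
#' on eCFT trials by a jittered 1-3 s gap and a 12-s counterfactual
#' simulation epoch, with 1.5-s fixations, odd/even numerical filler blocks
#' and button presses in between. Voxel signals place epoch-specific latent
#' patterns into FIR-consistent boxcar time courses over AR(1) noise; known
#' index dynamics are injected on the Fisher-z scale.
#'
#' @param n_subjects Number of subjects.
#' @param n_runs Functional runs per subject.
#' @param trials_per_condition Trials per condition per subject (equal
#'   across the three conditions).
#' @param tr_seconds Repetition time in seconds.
#' @param epoch_seconds Duration of each recall / CFT epoch.
#' @param jitter_choices Candidate recall-to-CFT gaps (subset of 1, 2, 3 s).
#' @param n_rois Number of atlas parcels carrying task patterns.
#' @param voxels_per_roi Voxels per parcel (>= 2).
#' @param drift_intercept True mean Recall-CFT similarity shift (Fisher-z)
#'   from the early (0-4 s) to the late (4-8 s) CFT window; negative values
#'   emulate divergence of the simulation from the memory.
#' @param anxiety_by_condition_slope True anxiety-moderation effect, in
#'   Fisher-z units per SD of trait anxiety, applied with sign +1 for
#'   upward and -1 for downward eCFT to both the shift and the
#'   within-condition CFT-CFT similarity.
#' @param base_recall_cft_z Baseline Recall-CFT similarity (Fisher-z).
#' @param base_cftcft_z Baseline within-condition CFT-CFT similarity
#'   (Fisher-z).
#' @param jitter_effect Autocorrelation artifact injected on the *early*
#'   Recall-CFT similarity: z-units added per second the gap falls short of
#'   the 2-s midpoint (shorter gap, higher spurious similarity). This is
#'   the nuisance structure the two-step residualization removes.
#' @param noise_sd Standard deviation of the AR(1) BOLD noise (latent
#'   patterns have unit variance).
#' @param ar1_coef Lag-1 autocorrelation of the noise, in \[0, 1).
#' @param outlier_rate Per-TR probability of a motion-outlier frame.
#' @param mask_coverage Fraction of each parcel's voxels inside the omnibus
#'   mask.
#' @param seed Integer RNG seed; identical config + seed reproduces the
#'   study bit for bit.
#' @return A validated `cftnps_synth_config` list.
#' @export
synth_config <- function(n_subjects = 40L, n_runs = 3L, trials_per_condition = 15L,
                         tr_seconds = 2, epoch_seconds = 12,
                         jitter_choices = c(1, 2, 3),
                         n_rois = 6L, voxels_per_roi = 100L,
                         drift_intercept = -0.05,
                         anxiety_by_condition_slope = 0.02,
                         base_recall_cft_z = 0.3, base_cftcft_z = 0.15,
                         jitter_effect = 0.02,
                         noise_sd = 0.2, ar1_coef = 0.3, outlier_rate = 0.02,
                         mask_coverage = 1, seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects), n_runs = as.integer(n_runs),
    trials_per_condition = as.integer(trials_per_condition),
    tr_seconds = tr_seconds, epoch_seconds = epoch_seconds,
    jitter_choices = jitter_choices, n_rois = as.integer(n_rois),
    voxels_per_roi = as.integer(voxels_per_roi),
    drift_intercept = drift_intercept,
    anxiety_by_condition_slope = anxiety_by_condition_slope,
    base_recall_cft_z = base_recall_cft_z, base_cftcft_z = base_cftcft_z,
    jitter_effect = jitter_effect,
    noise_sd = noise_sd, ar1_coef = ar1_coef, outlier_rate = outlier_rate,
    mask_coverage = mask_coverage, seed = as.integer(seed)
  )
  with(cfg, {
    stopifnot(
      n_subjects > 0, n_runs > 0, trials_per_condition > 0,
      tr_seconds > 0, epoch_seconds > 0,
      n_rois > 0, voxels_per_roi >= 2,
      ar1_coef >= 0, ar1_coef < 1,
      noise_sd >= 0, outlier_rate >= 0, outlier_rate <= 1,
      mask_coverage >= 0, mask_coverage <= 1,
      all(jitter_choices %in% c(1, 2, 3))
    )
  })
  class(cfg) <- "cftnps_synth_config"
  cfg
}

# AR(1) noise matrix, voxels x TRs, marginal sd = sd.
ar1_noise <- function(n_vox, n_tr, sd, phi) {
  if (sd == 0) return(matrix(0, n_vox, n_tr))
  e <- matrix(stats::rnorm(n_vox * n_tr), n_vox, n_tr)
  x <- e * sd
  if (phi > 0) {
    x[, 1] <- e[, 1] * sd
    innov_sd <- sd * sqrt(1 - phi^2)
    for (t in 2:n_tr) x[, t] <- phi * x[, t - 1] + e[, t] * innov_sd
  }
  x
}

#' Generate a complete synthetic study with known ground truth
#'
#' Produces BOLD runs, trial events, per-TR confounds with motion-outlier
#' flags, an atlas parcellation, an omnibus mask, a covariate table and a
#' ground-truth record for every eCFT trial. The latent CFT patterns are
#' mixtures of the trial's recall pattern, a subject-by-condition template
#' and a trial-specific component, with mixing weights chosen so that the
#' expected Fisher-z Recall-CFT correlations differ across CFT windows by
#' `drift_intercept + anxiety_by_condition_slope * anxiety_z * sign(cond)`,
#' and the expected within-condition CFT-CFT similarity equals
#' `base_cftcft_z + anxiety_by_condition_slope * anxiety_z * sign(cond)`.
#' Anxiety enters sample-standardized, the same scale on which the
#' mixed-effects models estimate their coefficients.
#'
#' @param config A [synth_config()].
#' @return A list: `runs` (list of `BoldRun`), `events` (trial table),
#'   `covariates`, `atlas`, `omnibus_mask`, `truth`, `config`.
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "cftnps_synth_config"))
  set.seed(config$seed)
  tr <- config$tr_seconds
  vpr <- config$voxels_per_roi
  n_rois <- config$n_rois
  n_vox <- (n_rois + 1L) * vpr          # block 1 = background (label 0)
  tpc <- config$trials_per_condition
  conds <- c("upward", "downward", "none")
  win_s <- 4
  n_win <- config$epoch_seconds / win_s
  if (n_win != round(n_win)) stop("generate_study: epoch length must be a multiple of 4 s")

  atlas <- array(0L, dim = c(vpr, n_rois + 1L, 1L))
  for (r in seq_len(n_rois)) atlas[, r + 1L, 1L] <- r
  mask <- array(0L, dim = dim(atlas))
  n_in <- round(config$mask_coverage * vpr)
  if (n_in > 0) for (r in seq_len(n_rois)) mask[seq_len(n_in), r + 1L, 1L] <- 1L
  roi_rows <- lapply(seq_len(n_rois), function(r) which(as.vector(atlas) == r))

  subjects <- sprintf("sub%02d", seq_len(config$n_subjects))
  anxiety <- round(stats::runif(config$n_subjects, 20, 70))
  anx_z <- as.vector(scale(anxiety))
  if (config$n_subjects == 1L) anx_z <- 0

  slope <- config$anxiety_by_condition_slope
  drift <- config$drift_intercept

  runs <- list()
  events_acc <- list()
  cov_acc <- list()
  truth_acc <- list()

  for (s in seq_len(config$n_subjects)) {
    sid <- subjects[s]
    az <- anx_z[s]
    # subject-level latent structure per ROI
    g_up <- stats::rnorm(n_vox)
    g_dn <- stats::rnorm(n_vox)
    filler_pat <- stats::rnorm(n_vox) * 0.5
    button_pat <- stats::rnorm(n_vox) * 0.2

    # memory -> condition assignment, then round-robin over runs
    mem_cond <- sample(rep(conds, each = tpc))
    arousal <- sample(1:7, 3L * tpc, replace = TRUE)
    mem_run <- integer(3L * tpc)
    for (cc in conds) {
      idx <- which(mem_cond == cc)
      mem_run[idx] <- rep_len(seq_len(config$n_runs), length(idx))
    }

    for (rn in seq_len(config$n_runs)) {
      rid <- paste0("run", rn)
      run_mems <- which(mem_run == rn)
      mems <- run_mems[sample.int(length(run_mems))]   # randomized trial order
      n_trials <- length(mems)
      onset <- 8                             # lead-in fixation
      ev <- vector("list", n_trials)
      filler_on <- c(); filler_dur <- c(); presses <- c()
      prev <- "no_previous"
      for (i in seq_len(n_trials)) {
        mem <- mems[i]
        cond <- mem_cond[mem]
        recall_onset <- onset
        presses <- c(presses, recall_onset + stats::runif(1, 1, 4))
        if (cond == "none") {
          cft_onset <- NA_real_; jit <- NA_real_
          t_end <- recall_onset + config$epoch_seconds
        } else {
          jit <- config$jitter_choices[sample.int(length(config$jitter_choices), 1L)]
          cft_onset <- recall_onset + config$epoch_seconds + jit
          presses <- c(presses, cft_onset + stats::runif(1, 1, 4))
          t_end <- cft_onset + config$epoch_seconds
        }
        n_num <- sample(2:4, 1L)
        f_on <- t_end + 1.5
        f_dur <- n_num * 1.5
        filler_on <- c(filler_on, f_on); filler_dur <- c(filler_dur, f_dur)
        presses <- c(presses, f_on + (seq_len(n_num) - 1) * 1.5 + stats::runif(n_num, 0.5, 1.2))
        ev[[i]] <- data.frame(
          subject_id = sid, run_id = rid, trial_index = i,
          memory_id = sprintf("mem%02d", mem), condition = cond,
          recall_onset = recall_onset, cft_onset = cft_onset,
          jitter_s = jit, prev_condition = prev, stringsAsFactors = FALSE
        )
        prev <- cond
        onset <- ceiling((f_on + f_dur) / tr) * tr
      }
      ev <- do.call(rbind, ev)
      n_tr <- ceiling((max(filler_on + filler_dur) + 12) / tr)

      # ----- confounds and outlier flags -----
      flags <- stats::runif(n_tr) < config$outlier_rate
      motion <- vapply(1:6, function(k) {
        as.vector(ar1_noise(1L, n_tr, 0.05, 0.5))
      }, numeric(n_tr))
      colnames(motion) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
      fd <- abs(stats::rnorm(n_tr, 0.1, 0.05))
      dvars <- abs(stats::rnorm(n_tr, 1.0, 0.1))
      fd[flags] <- stats::runif(sum(flags), 0.6, 1.5)
      dvars[flags] <- stats::runif(sum(flags), 1.6, 3)
      confounds <- data.frame(
        csf = as.vector(ar1_noise(1L, n_tr, 1, 0.3)),
        wm = as.vector(ar1_noise(1L, n_tr, 1, 0.3)),
        dvars = dvars, framewise_displacement = fd, motion
      )

      # ----- voxel signal -----
      signal <- ar1_noise(n_vox, n_tr, config$noise_sd, config$ar1_coef)
      if (any(flags)) {
        signal[, flags] <- signal[, flags] +
          matrix(stats::rnorm(n_vox * sum(flags), 0, 5 * config$noise_sd),
                 n_vox, sum(flags))
      }
      conv <- convolve_events(filler_on, filler_dur, tr, n_tr)
      signal <- signal + outer(filler_pat, conv[, "main"])
      convb <- convolve_events(presses, rep(0.1, length(presses)), tr, n_tr)
      signal <- signal + outer(button_pat, convb[, "main"])

      place <- function(pattern, onset, w) {
        idx <- epoch_tr_windows(onset, tr)[[w]] + 1L
        signal[, idx] <<- signal[, idx] + pattern
      }
      for (i in seq_len(nrow(ev))) {
        mem <- mems[i]
        cond <- ev$condition[i]
        # one sustained memory representation across the whole recall epoch:
        # keeps the unmodelled portion of this epoch (when another trial is
        # focal) a smooth 12-s plateau rather than window-wise white signal,
        # which would alias into the focal FIR columns of other trials
        m <- stats::rnorm(n_vox)           # recall pattern (memory representation)
        for (w in 1:3) place(m, ev$recall_onset[i], w)
        if (cond == "none") next
        sign_c <- if (cond == "upward") 1 else -1
        g <- if (cond == "upward") g_up else g_dn
        eps <- stats::rnorm(n_vox)
        z_cc <- config$base_cftcft_z + slope * az * sign_c
        b <- sqrt(max(tanh(z_cc), 0))
        z_early <- config$base_recall_cft_z + config$jitter_effect * (2 - ev$jitter_s[i])
        z_late <- config$base_recall_cft_z + drift + slope * az * sign_c
        a_e <- tanh(z_early); a_l <- tanh(z_late)
        c_e2 <- 1 - a_e^2 - b^2; c_l2 <- 1 - a_l^2 - b^2
        if (c_e2 < 0 || c_l2 < 0) {
          stop("generate_study: injected similarities exceed unit variance; ",
               "reduce base levels or effect sizes")
        }
        # early/late CFT patterns share the trial-specific component, so the
        # simulation epoch is a near-plateau whose early window deviates only
        # by the injected drift/moderation (the construction-vs-elaboration
        # dynamics the indices measure); the late pattern persists into the
        # final window
        place(a_e * m + b * g + sqrt(c_e2) * eps, ev$cft_onset[i], 1L)
        place(a_l * m + b * g + sqrt(c_l2) * eps, ev$cft_onset[i], 2L)
        place(a_l * m + b * g + sqrt(c_l2) * eps, ev$cft_onset[i], 3L)
        truth_acc[[length(truth_acc) + 1L]] <- data.frame(
          subject_id = sid, run_id = rid, memory_id = sprintf("mem%02d", mem),
          condition = cond, jitter_s = ev$jitter_s[i],
          anxiety = anxiety[s], anxiety_z = az, arousal = arousal[mem],
          z_early_true = z_early, z_late_true = z_late,
          shift_true_raw = z_late - z_early,
          shift_true_adjusted = drift + slope * az * sign_c,
          cc_z_true = z_cc, stringsAsFactors = FALSE
        )
      }
      runs[[length(runs) + 1L]] <- list(
        subject_id = sid, run_id = rid, tr_seconds = tr, signal = signal,
        confounds = confounds, outlier_flags = flags,
        filler_events = data.frame(onset = filler_on, duration = filler_dur),
        button_presses = sort(presses)
      )
      events_acc[[length(events_acc) + 1L]] <- ev
    }
    cov_acc[[s]] <- data.frame(
      subject_id = sid, stai_y2 = anxiety[s],
      memory_id = sprintf("mem%02d", seq_len(3L * tpc)),
      arousal = arousal, stringsAsFactors = FALSE
    )
  }

  list(
    runs = runs,
    events = do.call(rbind, events_acc),
    covariates = do.call(rbind, cov_acc),
    atlas = atlas,
    omnibus_mask = mask,
    truth = list(
      trials = do.call(rbind, truth_acc),
      subjects = data.frame(subject_id = subjects, stai_y2 = anxiety,
                            anxiety_z = anx_z, stringsAsFactors = FALSE),
      coef = list(
        shift_intercept = drift,
        slope_per_sign = slope,
        shift_interaction_upward_vs_downward = 2 * slope,
        cc_interaction_upward_vs_downward = 2 * slope
      )
    ),
    config = config
  )
}
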