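#' Build the Least-Squares-Separate design matrix for one focal trial
#'
#' Constructs the single-trial GLM design in which the focal trial's
#' epoch(s) are modelled with a finite impulse response (FIR) basis -- one
#' free column per 4-s window (2 TRs at TR = 2 s), three windows per 12-s
#' epoch -- while everything else in the run is nuisance:
#' \itemize{
#'   \item five categories of other events, convolved with the double-gamma
#'     HRF plus temporal derivatives: (i) all other recall epochs, (ii) all
#'     other upward-CFT epochs, (iii) all other downward-CFT epochs,
#'     (iv) odd/even numerical-judgment blocks, (v) button presses
#'     (0.1-s duration);
#'   \item confound time series (CSF, WM, DVARS, framewise displacement,
#'     six motion parameters);
#'   \item one indicator column per motion-outlier TR;
#'   \item discrete-cosine drift columns implementing a 100-s high-pass
#'     filter, plus an intercept.
#' }
#' Empty categories (e.g. a run with no flagged TRs) contribute no columns.
#'
#' @param focal One-row data frame: the focal trial (see
#'   [generate_study()] for the event schema).
#' @param all_events Data frame of all trials in the same run.
#' @param run A `BoldRun` list: `signal` (voxel x TR matrix), `tr_seconds`,
#'   `confounds` (per-TR data frame), `outlier_flags`, `filler_events`,
#'   `button_presses`.
#' @param highpass_s High-pass cutoff in seconds for the drift basis.
#' @param include_derivs,include_dct,include_confounds Ablation switches
#'   (all `TRUE` for the standard design); useful for studying how each
#'   column family shapes single-trial estimates on synthetic data.
#' @param precomp Optional per-run convolution cache from
#'   [precompute_run_regressors()]; the design is identical with or without
#'   it (convolution is linear), the cache only avoids recomputing shared
#'   regressors for every focal trial of a run.
#' @return A list with the design matrix `X`, per-column metadata
#'   `columns` (name, category), and `focal_cols` (names of the focal FIR
#'   columns, 3 for a No-eCFT recall, 6 for an eCFT trial).
#' @export
build_lss_design <- function(focal, all_events, run, highpass_s = 100,
                             include_derivs = TRUE, include_dct = TRUE,
                             include_confounds = TRUE, precomp = NULL) {
  tr <- run$tr_seconds
  n_tr <- ncol(run$signal)
  run_end <- n_tr * tr
  ev_end <- max(all_events$recall_onset + 12,
                all_events$cft_onset + 12, na.rm = TRUE)
  if (ev_end > run_end + 1e-9) {
    stop("build_lss_design: events extend past run end (", ev_end, " > ", run_end, " s)")
  }

  win_names <- c("w0_4", "w4_8", "w8_12")
  cols <- list()
  meta <- list()
  add <- function(x, name, category) {
    cols[[length(cols) + 1L]] <<- x
    meta[[length(meta) + 1L]] <<- data.frame(name = name, category = category)
  }

  fir_cols <- function(onset, prefix) {
    wins <- epoch_tr_windows(onset, tr)
    for (w in seq_along(wins)) {
      idx <- wins[[w]] + 1L
      if (max(idx) > n_tr) stop("build_lss_design: focal epoch extends past run end")
      v <- numeric(n_tr)
      v[idx] <- 1
      add(v, paste0(prefix, "_", win_names[w]), "focal_fir")
    }
  }
  fir_cols(focal$recall_onset, "focal_recall")
  if (focal$condition %in% c("upward", "downward")) {
    fir_cols(focal$cft_onset, "focal_cft")
  }
  focal_cols <- vapply(meta, function(m) m$name, character(1))

  add_cc <- function(cc, name) {
    if (is.null(cc) || max(abs(cc[, "main"])) < 1e-12) return(invisible(NULL))
    add(cc[, "main"], name, "nuisance_event")
    if (include_derivs) add(cc[, "deriv"], paste0(name, "_deriv"), "nuisance_event")
  }
  hrf_category <- function(onsets, durations, name) {
    keep <- !is.na(onsets)
    onsets <- onsets[keep]; durations <- durations[keep]
    if (length(onsets) == 0L) return(invisible(NULL))
    add_cc(convolve_events(onsets, durations, tr, n_tr), name)
  }
  if (!is.null(precomp)) {
    fi <- match(focal$memory_id, precomp$memory_id)
    add_cc(precomp$recall_total - precomp$recall[[fi]], "other_recall")
    up_cc <- precomp$cft_total_upward
    dn_cc <- precomp$cft_total_downward
    if (identical(focal$condition, "upward")) up_cc <- up_cc - precomp$cft[[fi]]
    if (identical(focal$condition, "downward")) dn_cc <- dn_cc - precomp$cft[[fi]]
    add_cc(up_cc, "other_upward_cft")
    add_cc(dn_cc, "other_downward_cft")
    add_cc(precomp$oddeven, "oddeven")
    add_cc(precomp$button, "button_press")
  } else {
    others <- all_events[all_events$memory_id != focal$memory_id |
                           all_events$subject_id != focal$subject_id, , drop = FALSE]
    hrf_category(others$recall_onset, rep(12, nrow(others)), "other_recall")
    up <- others[others$condition == "upward", , drop = FALSE]
    dn <- others[others$condition == "downward", , drop = FALSE]
    hrf_category(up$cft_onset, rep(12, nrow(up)), "other_upward_cft")
    hrf_category(dn$cft_onset, rep(12, nrow(dn)), "other_downward_cft")
    if (!is.null(run$filler_events) && nrow(run$filler_events) > 0) {
      hrf_category(run$filler_events$onset, run$filler_events$duration, "oddeven")
    }
    if (!is.null(run$button_presses) && length(run$button_presses) > 0) {
      hrf_category(run$button_presses, rep(0.1, length(run$button_presses)), "button_press")
    }
  }

  if (include_confounds) {
    for (nm in intersect(c("csf", "wm", "dvars", "framewise_displacement",
                           "trans_x", "trans_y", "trans_z",
                           "rot_x", "rot_y", "rot_z"),
                         names(run$confounds))) {
      add(run$confounds[[nm]], nm, "confound")
    }
  }
  for (i in which(run$outlier_flags)) {
    v <- numeric(n_tr)
    v[i] <- 1
    add(v, paste0("outlier_tr", i), "outlier")
  }
  # SPM-style discrete cosine high-pass basis (constant term excluded)
  if (include_dct) {
    K <- floor(2 * n_tr * tr / highpass_s)
    t0 <- seq_len(n_tr) - 0.5
    for (k in seq_len(K)) {
      add(cos(pi * k * t0 / n_tr), paste0("dct", k), "drift")
    }
  }
  add(rep(1, n_tr), "intercept", "intercept")

  X <- do.call(cbind, cols)
  columns <- do.call(rbind, meta)
  colnames(X) <- columns$name
  # Temporal-derivative regressors are orthogonalized against the focal FIR
  # block: a derivative column exists to absorb response-timing variation
  # of its own pooled events, but its sharp on/offset transients overlap
  # the focal windows by construction and otherwise leach window-specific
  # focal signal. Orthogonalization is an attribution choice only -- the
  # model span, fitted values and residuals are unchanged. The convolved
  # event regressors themselves and all noise regressors (confounds,
  # outlier indicators, drift) keep their full overlap: signal genuinely
  # shared with them must stay attributable to them.
  dcols <- grep("_deriv$", columns$name)
  if (length(dcols) > 0) {
    Fb <- X[, columns$category == "focal_fir", drop = FALSE]
    proj <- Fb %*% solve(crossprod(Fb), crossprod(Fb, X[, dcols, drop = FALSE]))
    X[, dcols] <- X[, dcols, drop = FALSE] - proj
  }
  list(X = X, columns = columns, focal_cols = focal_cols, n_tr = n_tr)
}

#' Precompute per-run convolved event regressors for the LSS sweep
#'
#' Every focal trial of a run shares almost all of its nuisance event
#' regressors with the other focal trials (categories differ only by which
#' trial is carved out as focal). This computes each trial's convolved
#' recall and CFT responses once, plus the filler and button-press
#' regressors and category totals, so [build_lss_design()] can assemble
#' any focal design by subtraction.
#'
#' @param run A `BoldRun` list.
#' @param events Trial events for this run.
#' @return A cache list consumed via the `precomp` argument of
#'   [build_lss_design()].
#' @export
precompute_run_regressors <- function(run, events) {
  tr <- run$tr_seconds
  n_tr <- ncol(run$signal)
  zero <- cbind(main = numeric(n_tr), deriv = numeric(n_tr))
  recall <- lapply(events$recall_onset, function(on) convolve_events(on, 12, tr, n_tr))
  cft <- lapply(seq_len(nrow(events)), function(i) {
    if (is.na(events$cft_onset[i])) zero
    else convolve_events(events$cft_onset[i], 12, tr, n_tr)
  })
  sum_cc <- function(lst) if (length(lst) == 0L) zero else Reduce(`+`, lst, zero)
  list(
    memory_id = events$memory_id,
    recall = recall, cft = cft,
    recall_total = sum_cc(recall),
    cft_total_upward = sum_cc(cft[events$condition == "upward"]),
    cft_total_downward = sum_cc(cft[events$condition == "downward"]),
    oddeven = if (is.null(run$filler_events) || nrow(run$filler_events) == 0) NULL
              else convolve_events(run$filler_events$onset, run$filler_events$duration, tr, n_tr),
    button = if (is.null(run$button_presses) || length(run$button_presses) == 0) NULL
             else convolve_events(run$button_presses, rep(0.1, length(run$button_presses)), tr, n_tr)
  )
}

#' Fit the single-trial GLM and return focal-window pattern maps
#'
#' Ordinary least squares per voxel; for each focal FIR column the map of
#' t-statistics \eqn{t = \hat\beta / \mathrm{SE}(\hat\beta)} with residual
#' degrees of freedom `TRs - rank(X)` is returned alongside the raw
#' coefficient map. The t-statistic (not the beta) is the pattern currency
#' downstream.
#'
#' @param run A `BoldRun` list (see [build_lss_design()]).
#' @param design Design list from [build_lss_design()].
#' @return List with `beta` and `t` (voxel x focal-window matrices), `df`
#'   (residual degrees of freedom), `sigma` (per-voxel residual SD) and
#'   `focal_cols`.
#' @details A rank-deficient design is an error naming the dependent
#'   columns. Voxels whose residual variance is numerically zero (an
#'   exact-fit, noise-free model) have no defined t; the coefficient itself
#'   is used as the pattern value for those voxels, with a warning, so that
#'   degenerate noiseless inputs remain analyzable.
#' @export
fit_trial_glm <- function(run, design) {
  X <- design$X
  Y <- t(run$signal)                      # TR x voxel
  if (nrow(Y) != nrow(X)) stop("fit_trial_glm: design rows do not match TR count")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("fit_trial_glm: rank-deficient design; dependent columns: ",
         paste(bad, collapse = ", "))
  }
  df <- nrow(X) - qx$rank
  if (df <= 0) stop("fit_trial_glm: non-positive residual degrees of freedom")
  beta <- qr.coef(qx, Y)                  # p x voxel
  res <- Y - X %*% beta
  sigma2 <- colSums(res^2) / df
  R <- qr.R(qx)
  xtx_inv <- chol2inv(R)
  dimnames(xtx_inv) <- list(colnames(X)[qx$pivot], colnames(X)[qx$pivot])
  jj <- design$focal_cols
  se_unit <- sqrt(diag(xtx_inv)[jj])      # per focal column, up to sigma
  b <- t(beta[jj, , drop = FALSE])        # voxel x focal window
  degenerate <- sigma2 < 1e-16
  sig <- sqrt(sigma2)
  tmat <- b / (outer(sig, se_unit))
  if (any(degenerate)) {
    warning("fit_trial_glm: ", sum(degenerate),
            " voxel(s) with zero residual variance; using coefficients as pattern values")
    tmat[degenerate, ] <- b[degenerate, , drop = FALSE]
  }
  list(beta = b, t = tmat, df = df, sigma = sig, focal_cols = jj)
}

#' Motion-based trial exclusion rule
#'
#' A focal trial is excluded when three or more of the six TRs covering a
#' focal 12-s epoch are flagged as motion outliers (frames exceeding 0.5-mm
#' framewise displacement or 1.5 standardized DVARS, flagged upstream). For
#' eCFT trials both focal epochs (recall and CFT) are checked; the trial is
#' excluded if either epoch crosses the threshold.
#'
#' @param focal One-row event data frame.
#' @param run A `BoldRun` list with `outlier_flags`.
#' @param threshold Minimum flagged-TR count that triggers exclusion.
#' @return `TRUE` if the trial is excluded.
#' @export
apply_motion_exclusion <- function(focal, run, threshold = 3L) {
  tr <- run$tr_seconds
  n_tr <- length(run$outlier_flags)
  count_epoch <- function(onset) {
    idx <- unlist(epoch_tr_windows(onset, tr)) + 1L
    if (max(idx) > n_tr) stop("apply_motion_exclusion: epoch extends past run end")
    sum(run$outlier_flags[idx])
  }
  n_flag <- count_epoch(focal$recall_onset)
  if (focal$condition %in% c("upward", "downward")) {
    n_flag <- max(n_flag, count_epoch(focal$cft_onset))
  }
  n_flag >= threshold
}

# TRUE when motion censoring swallows an entire focal FIR window (the
# window's indicator column would be a sum of outlier columns, leaving the
# window amplitude unidentifiable). Such trials are excluded alongside the
# >= 3-of-6 rule: both are motion-driven losses.
trial_window_censored <- function(focal, run) {
  tr <- run$tr_seconds
  onsets <- focal$recall_onset
  if (focal$condition %in% c("upward", "downward")) onsets <- c(onsets, focal$cft_onset)
  for (on in onsets) {
    for (w in epoch_tr_windows(on, tr)) {
      if (all(run$outlier_flags[w + 1L])) return(TRUE)
    }
  }
  FALSE
}

#' Extract per-ROI pattern vectors from focal-window statistic maps
#'
#' @param tmaps Voxel x window matrix of statistics (rows in flat volume
#'   order).
#' @param atlas Integer atlas volume (array or flat vector on the same
#'   voxel grid; label 0 is background).
#' @param rois Integer vector of ROI labels to extract.
#' @return Named list (by ROI label) of voxel x window matrices.
#' @export
extract_roi_patterns <- function(tmaps, atlas, rois) {
  a <- as.integer(as.vector(atlas))
  if (length(a) != nrow(tmaps)) stop("extract_roi_patterns: atlas and maps differ in voxel grid")
  out <- lapply(rois, function(lab) {
    idx <- which(a == lab)
    if (length(idx) == 0L) stop("extract_roi_patterns: ROI label ", lab, " absent from atlas")
    tmaps[idx, , drop = FALSE]
  })
  names(out) <- as.character(rois)
  out
}

#' Estimate all focal-trial window patterns for a synthetic or loaded study
#'
#' Runs the full single-trial stage: for every eCFT trial of every run,
#' applies the motion exclusion rule, builds the LSS design, fits the GLM,
#' and extracts per-ROI t-statistic patterns for the six focal windows
#' (three recall, three CFT).
#'
#' @param study Study list from [generate_study()] (or [read_study()]).
#' @param rois Integer ROI labels to extract (typically the retained set
#'   from [select_rois()]).
#' @param pattern_stat `"t"` (default; t-statistic maps are the standard
#'   pattern currency for this analysis) or `"beta"`.
#' @param highpass_s High-pass cutoff passed to [build_lss_design()].
#' @param motion_threshold Flagged-TR count per focal epoch that triggers
#'   exclusion (see [apply_motion_exclusion()]).
#' @return Data frame with one row per trial x epoch x window x ROI:
#'   identifiers, `excluded` flag, `zero_var` flag and a `pattern`
#'   list-column of voxel vectors (`NULL` when excluded).
#' @export
extract_study_patterns <- function(study, rois, pattern_stat = c("t", "beta"),
                                   highpass_s = 100, motion_threshold = 3L) {
  pattern_stat <- match.arg(pattern_stat)
  win_names <- c("w0_4", "w4_8", "w8_12")
  acc <- list()   # list of per-trial blocks of parallel columns
  for (run in study$runs) {
    ev <- study$events[study$events$subject_id == run$subject_id &
                         study$events$run_id == run$run_id, , drop = FALSE]
    focals <- ev[ev$condition %in% c("upward", "downward"), , drop = FALSE]
    pc <- precompute_run_regressors(run, ev)
    for (i in seq_len(nrow(focals))) {
      focal <- focals[i, , drop = FALSE]
      excl <- apply_motion_exclusion(focal, run, threshold = motion_threshold) ||
        trial_window_censored(focal, run)
      by_roi <- NULL
      if (!excl) {
        des <- build_lss_design(focal, ev, run, highpass_s = highpass_s,
                                precomp = pc)
        fit <- fit_trial_glm(run, des)
        maps <- if (pattern_stat == "t") fit$t else fit$beta
        by_roi <- extract_roi_patterns(maps, study$atlas, rois)
      }
      grid <- expand.grid(window = win_names, epoch = c("recall", "cft"),
                          roi_label = rois, stringsAsFactors = FALSE)
      pats <- vector("list", nrow(grid))
      zv <- rep(NA, nrow(grid))
      if (!excl) {
        for (k in seq_len(nrow(grid))) {
          cn <- paste0("focal_", grid$epoch[k], "_", grid$window[k])
          pats[[k]] <- by_roi[[as.character(grid$roi_label[k])]][, cn]
          zv[k] <- stats::sd(pats[[k]]) == 0
        }
      }
      blk <- data.frame(
        subject_id = focal$subject_id, run_id = focal$run_id,
        memory_id = focal$memory_id, condition = focal$condition,
        jitter_s = focal$jitter_s, prev_condition = focal$prev_condition,
        epoch = grid$epoch, window = grid$window, roi_label = grid$roi_label,
        excluded = excl, zero_var = zv, stringsAsFactors = FALSE
      )
      blk$pattern <- I(pats)
      acc[[length(acc) + 1L]] <- blk
    }
  }
  out <- do.call(rbind, acc)
  rownames(out) <- NULL
  out
}
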