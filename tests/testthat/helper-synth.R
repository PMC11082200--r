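# Shared small fixtures, generated in code and cached per test session.

.fixtures <- new.env(parent = emptyenv())

# a small but complete study: 3 subjects, 6 trials/condition, 2 ROIs
tiny_study <- function() {
  if (is.null(.fixtures$tiny)) {
    cfg <- synth_config(n_subjects = 3, trials_per_condition = 6, n_rois = 2,
                        voxels_per_roi = 60, noise_sd = 0.2, seed = 417)
    .fixtures$tiny <- generate_study(cfg)
  }
  .fixtures$tiny
}

# balanced trial-level index records for mixed-model tests: every subject
# contributes n_per_cell trials per condition x jitter x prev cell
make_index_records <- function(n_subjects = 12, n_per_cell = 2,
                               b_cond = 0, b_anx = 0, b_interact = 0,
                               intercept = 0, nuisance_jitter = c(0, 0, 0),
                               nuisance_prev = c(0, 0, 0, 0),
                               sd_subject = 0.02, sd_trial = 0.05,
                               roi_label = 1L, seed = 1,
                               balanced_arousal = FALSE) {
  set.seed(seed)
  jits <- c(1, 2, 3)
  prevs <- c("upward", "downward", "none", "no_previous")
  grid <- expand.grid(condition = c("downward", "upward"), jitter_s = jits,
                      prev_condition = prevs, rep = seq_len(n_per_cell),
                      stringsAsFactors = FALSE)
  anx <- rnorm(n_subjects)
  # inject on the sample-standardized scale: with balanced rows per subject
  # the model's row-wise z-scoring of anxiety recovers exactly this scale
  anx_z <- as.vector(scale(anx))
  rows <- lapply(seq_len(n_subjects), function(s) {
    u <- rnorm(1, 0, sd_subject)
    g <- grid
    g$subject_id <- sprintf("s%02d", s)
    g$anxiety <- 40 + 10 * anx[s]
    # balanced_arousal ties arousal to the replicate id so it is exactly
    # orthogonal to every nuisance cell (needed for exact two-step /
    # one-step equivalence); otherwise arousal is a random rating
    g$arousal <- if (balanced_arousal) 1 + (g$rep %% 7)
                 else sample(1:7, nrow(g), replace = TRUE)
    cs <- ifelse(g$condition == "upward", 1, 0)
    g$value <- intercept + u +
      b_cond * cs + b_anx * anx_z[s] + b_interact * anx_z[s] * cs +
      nuisance_jitter[match(g$jitter_s, jits)] +
      nuisance_prev[match(g$prev_condition, prevs)] +
      rnorm(nrow(g), 0, sd_trial)
    g
  })
  out <- do.call(rbind, rows)
  out$memory_id <- sprintf("mem%03d", seq_len(nrow(out)))
  out$roi_label <- roi_label
  out$index_kind <- "recall_cft_shift_raw"
  out$m <- NA_integer_
  out
}
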