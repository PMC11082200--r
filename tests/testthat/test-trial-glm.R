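study <- NULL
first_run <- function() {
  st <- tiny_study()
  list(st = st, run = st$runs[[1]],
       ev = st$events[st$events$subject_id == st$runs[[1]]$subject_id &
                        st$events$run_id == st$runs[[1]]$run_id, ])
}

test_that("FIR columns sit exactly on the 2-TR windows of the focal epochs", {
  f <- first_run()
  focal <- f$ev[f$ev$condition %in% c("upward", "downward"), ][1, ]
  des <- build_lss_design(focal, f$ev, f$run)
  # an eCFT trial contributes exactly 6 focal FIR columns
  expect_length(des$focal_cols, 6)
  expect_identical(sum(des$columns$category == "focal_fir"), 6L)
  # direct construction oracle for a grid-aligned onset
  tr <- f$run$tr_seconds
  t0 <- focal$recall_onset
  expect_identical(t0 %% tr, 0)   # generator aligns recall onsets
  col <- des$X[, "focal_recall_w0_4"]
  want <- numeric(length(col))
  want[floor(t0 / tr) + c(1, 2)] <- 1
  expect_identical(col, want)
  # windows tile the epoch: 6 TRs covered once each per epoch
  recall_cols <- des$X[, c("focal_recall_w0_4", "focal_recall_w4_8", "focal_recall_w8_12")]
  expect_identical(sum(recall_cols), 6)
  expect_true(all(rowSums(recall_cols) <= 1))
  # a No-eCFT focal trial would carry only the 3 recall windows
  none <- f$ev[f$ev$condition == "none", ][1, ]
  expect_length(build_lss_design(none, f$ev, f$run)$focal_cols, 3)
})

test_that("outlier indicator columns appear only for flagged TRs", {
  f <- first_run()
  focal <- f$ev[f$ev$condition %in% c("upward", "downward"), ][1, ]
  run0 <- f$run
  run0$outlier_flags[] <- FALSE
  des0 <- build_lss_design(focal, f$ev, run0)
  expect_identical(sum(des0$columns$category == "outlier"), 0L)
  run0$outlier_flags[c(4, 9)] <- TRUE
  des2 <- build_lss_design(focal, f$ev, run0)
  expect_identical(sum(des2$columns$category == "outlier"), 2L)
})

test_that("noiseless signal built from the design is recovered exactly", {
  f <- first_run()
  focal <- f$ev[f$ev$condition %in% c("upward", "downward"), ][2, ]
  des <- build_lss_design(focal, f$ev, f$run)
  set.seed(99)
  n_vox <- 50
  B <- matrix(rnorm(ncol(des$X) * n_vox), ncol(des$X), n_vox)
  run2 <- f$run
  run2$signal <- t(des$X %*% B)
  fit <- suppressWarnings(fit_trial_glm(run2, des))
  expect_equal(fit$beta, t(B[match(des$focal_cols, colnames(des$X)), ]),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("pure-noise voxels give t-statistics centred on zero", {
  f <- first_run()
  focal <- f$ev[f$ev$condition %in% c("upward", "downward"), ][1, ]
  des <- build_lss_design(focal, f$ev, f$run)
  set.seed(123)
  run2 <- f$run
  n_vox <- 4000
  run2$signal <- matrix(rnorm(n_vox * ncol(f$run$signal)), n_vox)
  fit <- fit_trial_glm(run2, des)
  tt <- fit$t[, "focal_cft_w4_8"]
  expect_lt(abs(mean(tt)), 3 * sd(tt) / sqrt(n_vox))
})

test_that("a duplicated regressor is reported as rank deficiency", {
  f <- first_run()
  focal <- f$ev[f$ev$condition %in% c("upward", "downward"), ][1, ]
  des <- build_lss_design(focal, f$ev, f$run)
  des$X <- cbind(des$X, dup = des$X[, "csf"])
  expect_error(fit_trial_glm(f$run, des), "rank-deficient")
})

test_that("motion exclusion triggers at three of six epoch TRs", {
  f <- first_run()
  focal <- f$ev[f$ev$condition %in% c("upward", "downward"), ][1, ]
  run0 <- f$run
  run0$outlier_flags[] <- FALSE
  epoch_trs <- floor(focal$recall_onset / run0$tr_seconds) + 1:6
  expect_false(apply_motion_exclusion(focal, run0))          # 0 flagged
  run0$outlier_flags[epoch_trs[1:2]] <- TRUE
  expect_false(apply_motion_exclusion(focal, run0))          # 2 flagged
  run0$outlier_flags[epoch_trs[3]] <- TRUE
  expect_true(apply_motion_exclusion(focal, run0))           # 3 flagged
  run0$outlier_flags[epoch_trs] <- TRUE
  expect_true(apply_motion_exclusion(focal, run0))           # 6 flagged
})

test_that("ROI extraction partitions voxels and validates labels", {
  st <- tiny_study()
  n_vox <- length(as.vector(st$atlas))
  tmaps <- matrix(rnorm(n_vox * 6), n_vox, 6,
                  dimnames = list(NULL, paste0("w", 1:6)))
  pats <- extract_roi_patterns(tmaps, st$atlas, 1:2)
  expect_identical(nrow(pats[["1"]]), st$config$voxels_per_roi)
  # disjoint ROIs share no voxels: recovered rows reassemble without overlap
  expect_identical(nrow(pats[["1"]]) + nrow(pats[["2"]]),
                   sum(as.vector(st$atlas) > 0))
  expect_error(extract_roi_patterns(tmaps, st$atlas, 99), "absent")
})

test_that("focal estimates are invariant to the ordering of other trials", {
  f <- first_run()
  focal <- f$ev[f$ev$condition %in% c("upward", "downward"), ][1, ]
  des1 <- build_lss_design(focal, f$ev, f$run)
  ev_shuffled <- f$ev[rev(seq_len(nrow(f$ev))), ]
  des2 <- build_lss_design(focal, ev_shuffled, f$run)
  fit1 <- fit_trial_glm(f$run, des1)
  fit2 <- fit_trial_glm(f$run, des2)
  expect_equal(fit1$t, fit2$t, tolerance = 1e-10)
})

test_that("every non-excluded eCFT trial yields 6 window patterns per ROI", {
  st <- tiny_study()
  pat <- suppressWarnings(extract_study_patterns(st, 1:2))
  ok <- pat[!pat$excluded, ]
  counts <- table(paste(ok$subject_id, ok$run_id, ok$memory_id, ok$roi_label))
  expect_true(all(counts == 6))
  ecft <- st$events[st$events$condition != "none", ]
  n_excl <- length(unique(paste(pat$subject_id, pat$run_id, pat$memory_id)[pat$excluded]))
  expect_identical(length(unique(paste(ok$subject_id, ok$run_id, ok$memory_id))) + n_excl,
                   nrow(ecft))
})

test_that("the precomputed-regressor path reproduces the direct design", {
  f <- first_run()
  pc <- precompute_run_regressors(f$run, f$ev)
  focal <- f$ev[f$ev$condition %in% c("upward", "downward"), ][3, ]
  d1 <- build_lss_design(focal, f$ev, f$run)
  d2 <- build_lss_design(focal, f$ev, f$run, precomp = pc)
  expect_identical(colnames(d1$X), colnames(d2$X))
  expect_equal(d1$X, d2$X, tolerance = 1e-10)
})
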