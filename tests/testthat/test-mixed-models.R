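test_that("fdr_correct matches p.adjust boundary examples and validates input", {
  r <- fdr_correct(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_equal(r$p_adjusted, rep(0.04, 4))
  expect_true(all(r$reject))
  expect_equal(fdr_correct(0.03)$p_adjusted, 0.03)
  expect_false(any(fdr_correct(rep(1, 5))$reject))
  expect_error(fdr_correct(numeric(0)), "empty")
  expect_error(fdr_correct(c(0.5, 1.2)), "0, 1")
})

test_that("fdr_correct equals a literal step-up reference on random vectors", {
  set.seed(101)
  for (i in 1:60) {
    m <- sample(1:40, 1)
    p <- runif(m)^sample(1:3, 1)
    expect_equal(fdr_correct(p)$p_adjusted, oracle_bh_adjust(p), tolerance = 1e-12)
  }
})

test_that("the moderation model recovers injected coefficients on its own scale", {
  rec <- make_index_records(n_subjects = 30, n_per_cell = 2, intercept = -0.05,
                            b_cond = 0.01, b_anx = -0.01, b_interact = 0.04,
                            sd_subject = 0.02, sd_trial = 0.05, seed = 42)
  fit <- fit_index_lmem(rec)
  est <- fit$terms$estimate
  names(est) <- fit$terms$term
  se <- fit$terms$se
  names(se) <- fit$terms$term
  for (chk in list(c("(Intercept)", -0.05), c("conditionupward", 0.01),
                   c("anxiety_z", -0.01), c("conditionupward:anxiety_z", 0.04))) {
    nm <- chk[1]; truth <- as.numeric(chk[2])
    expect_lt(abs(est[nm] - truth), 3 * se[nm])
  }
  expect_true(all(fit$terms$df > 0))
  expect_true(all(fit$terms$p >= 0 & fit$terms$p <= 1))
})

test_that("simple slopes are the exact linear combinations of fixed effects", {
  rec <- make_index_records(n_subjects = 20, b_anx = -0.02, b_interact = 0.05,
                            sd_trial = 0.05, seed = 7)
  fit <- fit_index_lmem(rec)
  sl <- simple_slopes(fit)
  fe <- lme4::fixef(fit$fit)
  expect_equal(sl$slope[sl$condition == "downward"],
               unname(fe["anxiety_z"]), tolerance = 1e-8)
  expect_equal(sl$slope[sl$condition == "upward"],
               unname(fe["anxiety_z"] + fe["conditionupward:anxiety_z"]),
               tolerance = 1e-8)
  # slope difference equals the interaction coefficient (treatment coding)
  expect_equal(diff(sl$slope[match(c("downward", "upward"), sl$condition)]),
               unname(fe["conditionupward:anxiety_z"]), tolerance = 1e-8)
  # refit oracle: with no subject variance the per-condition OLS fit gives
  # the same anxiety slope as the simple-slope contrast
  rec0 <- make_index_records(n_subjects = 40, b_anx = -0.02, b_interact = 0.05,
                             sd_subject = 0, sd_trial = 0.03, seed = 8)
  f0 <- fit_index_lmem(rec0)
  s0 <- simple_slopes(f0)
  for (cond in c("downward", "upward")) {
    d <- rec0[rec0$condition == cond, ]
    d$anxiety_z <- (d$anxiety - mean(rec0$anxiety)) / sd(rec0$anxiety)
    d$arousal_z <- (d$arousal - mean(rec0$arousal)) / sd(rec0$arousal)
    ols <- coef(lm(value ~ anxiety_z * arousal_z, data = d))[["anxiety_z"]]
    expect_equal(s0$slope[s0$condition == cond], ols, tolerance = 5e-3)
  }
})

test_that("relabelling the conditions swaps slopes but preserves the interaction", {
  rec <- make_index_records(n_subjects = 16, b_interact = 0.04, seed = 21)
  fit1 <- fit_index_lmem(rec)
  rec2 <- rec
  rec2$condition <- ifelse(rec$condition == "upward", "downward", "upward")
  fit2 <- fit_index_lmem(rec2)
  s1 <- simple_slopes(fit1); s2 <- simple_slopes(fit2)
  expect_equal(s1$slope[s1$condition == "upward"],
               s2$slope[s2$condition == "downward"], tolerance = 1e-6)
  expect_equal(s1$slope[s1$condition == "downward"],
               s2$slope[s2$condition == "upward"], tolerance = 1e-6)
  i1 <- fit1$terms[fit1$terms$term == "conditionupward:anxiety_z", ]
  i2 <- fit2$terms[fit2$terms$term == "conditionupward:anxiety_z", ]
  expect_equal(abs(i1$t), abs(i2$t), tolerance = 1e-6)
  expect_equal(i1$p, i2$p, tolerance = 1e-6)
})

test_that("duplicated subjects leave fixed-effect estimates unchanged", {
  rec <- make_index_records(n_subjects = 10, b_interact = 0.03, seed = 33)
  dup <- rec
  dup$subject_id <- paste0(dup$subject_id, "_copy")
  both <- rbind(rec, dup)
  f1 <- fit_index_lmem(rec)
  f2 <- fit_index_lmem(both)
  # REML variance components shift slightly with the doubled sample, so the
  # fixed effects agree to optimizer precision rather than exactly
  expect_lt(max(abs(f1$terms$estimate - f2$terms$estimate)), 1e-3)
})

test_that("degenerate inputs are rejected with informative errors", {
  rec <- make_index_records(n_subjects = 6, seed = 2)
  expect_error(fit_index_lmem(rec[rec$condition == "upward", ]), "one condition")
  expect_error(fit_index_lmem(rec[rec$subject_id == "s01", ]), "2 subjects")
})

test_that("the ROI sweep reports every ROI, applies per-term FDR, and survives failures", {
  set.seed(61)
  rois <- 1:6
  tabs <- lapply(rois, function(r) {
    g <- if (r <= 2) 0.08 else 0            # strong effect in ROIs 1 and 2 only
    out <- make_index_records(n_subjects = 14, b_interact = g, sd_trial = 0.04,
                              seed = 100 + r)
    out$roi_label <- r
    out
  })
  tab <- do.call(rbind, tabs)
  sw <- run_roi_sweep(tab)
  expect_identical(sort(unique(sw$results$roi_label)), rois)
  inter <- sw$results[sw$results$term == "conditionupward:anxiety_z", ]
  expect_true(all(inter$significant[inter$roi_label <= 2]))
  expect_lte(sum(inter$significant[inter$roi_label > 2]), 1)
  # FDR within a degenerate all-ties family equals the raw p
  clone <- do.call(rbind, lapply(1:4, function(r) { x <- tabs[[3]]; x$roi_label <- r; x }))
  swc <- run_roi_sweep(clone)
  expect_equal(swc$results$p_fdr, swc$results$p, tolerance = 1e-10)
  # a broken ROI does not abort the sweep
  bad <- tabs[[4]]
  bad$condition <- "upward"
  sw2 <- run_roi_sweep(rbind(tab, transform(bad, roi_label = 99L)))
  expect_identical(sw2$failures$roi_label, 99L)
  expect_identical(sort(unique(sw2$results$roi_label)), rois)
})

test_that("at the null the interaction rejects at close to nominal rate", {
  set.seed(77)
  ps <- replicate(40, {
    rec <- make_index_records(n_subjects = 12, n_per_cell = 1, sd_trial = 0.05,
                              seed = sample.int(1e6, 1))
    f <- fit_index_lmem(rec)
    f$terms$p[f$terms$term == "conditionupward:anxiety_z"]
  })
  expect_lt(mean(ps < 0.05), 0.18)
  expect_gt(mean(ps), 0.25)   # p-values roughly uniform, not degenerate
})
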