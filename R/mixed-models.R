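#' Fit the per-ROI linear mixed-effects moderation model for one index
#'
#' Restricted-maximum-likelihood mixed model of a trial-level similarity
#' index on the full factorial of eCFT condition (downward reference) x
#' trait anxiety x baseline arousal, with a random intercept per subject.
#' Continuous predictors are mean-centered and standardized (z-scored over
#' observations) before entry. Wald t-tests use Satterthwaite-approximated
#' denominator degrees of freedom by default (hence possibly fractional
#' df), with Kenward-Roger as an option.
#'
#' @param records Index records for a single ROI and index kind, with
#'   columns `value`, `condition`, `anxiety`, `arousal`, `subject_id` (and
#'   `jitter_s`, `prev_condition` if `include_nuisance`). `NA` values are
#'   dropped.
#' @param include_nuisance Also include the recall-to-CFT interval and
#'   previous-trial condition as categorical nuisance fixed effects (for
#'   modelling a *raw* index in one step instead of the two-step
#'   residualize-then-model route).
#' @param three_way Keep the condition x anxiety x arousal three-way term
#'   (default); `FALSE` restricts to pairwise interactions.
#' @param df_method `"satterthwaite"` (default) or `"kenward-roger"`.
#' @param random_structure `"subject"` (default): the conventional
#'   participant-level random intercept. `"subject_by_condition"` adds a
#'   nested random intercept per subject x condition cell — advisable for
#'   the CFT-CFT index, whose trial records share cross-run comparison
#'   pools and are therefore positively dependent within a subject's
#'   condition; with only a subject-level intercept the trial-level Wald
#'   tests for condition terms are anticonservative (see the methods
#'   vignette).
#' @return A `cftnps_lmem` object: `terms` (data frame of estimate, SE, df,
#'   t, p per fixed effect), the underlying `fit`, `converged` and
#'   `singular` flags, `n_obs`, `n_subjects`.
#' @export
fit_index_lmem <- function(records, include_nuisance = FALSE, three_way = TRUE,
                           df_method = c("satterthwaite", "kenward-roger"),
                           random_structure = c("subject", "subject_by_condition")) {
  df_method <- match.arg(df_method)
  random_structure <- match.arg(random_structure)
  d <- records[!is.na(records$value), , drop = FALSE]
  if (length(unique(d$subject_id)) < 2) {
    stop("fit_index_lmem: need at least 2 subjects")
  }
  if (length(unique(d$condition)) < 2) {
    stop("fit_index_lmem: all observations in one condition")
  }
  d$condition <- factor(d$condition, levels = c("downward", "upward"))
  d$anxiety_z <- as.vector(scale(d$anxiety))
  d$arousal_z <- as.vector(scale(d$arousal))
  rhs <- if (three_way) "condition * anxiety_z * arousal_z"
         else "(condition + anxiety_z + arousal_z)^2"
  if (include_nuisance) {
    rhs <- paste(rhs, "+ factor(jitter_s) + factor(prev_condition)")
  }
  ranef_term <- switch(random_structure,
    subject = "(1 | subject_id)",
    subject_by_condition = "(1 | subject_id) + (1 | subject_id:condition)")
  form <- stats::as.formula(paste("value ~", rhs, "+", ranef_term))
  fit <- lmerTest::lmer(form, data = d, REML = TRUE)
  msgs <- fit@optinfo$conv$lme4$messages
  converged <- is.null(msgs) || !any(grepl("failed to converge", msgs))
  coefs <- stats::coef(summary(fit, ddf = switch(df_method,
    satterthwaite = "Satterthwaite", `kenward-roger` = "Kenward-Roger")))
  terms <- data.frame(
    term = rownames(coefs),
    estimate = coefs[, "Estimate"], se = coefs[, "Std. Error"],
    df = coefs[, "df"], t = coefs[, "t value"], p = coefs[, "Pr(>|t|)"],
    row.names = NULL
  )
  structure(list(
    fit = fit, terms = terms, df_method = df_method,
    converged = converged, singular = lme4::isSingular(fit),
    n_obs = nrow(d), n_subjects = length(unique(d$subject_id))
  ), class = "cftnps_lmem")
}

#' @export
print.cftnps_lmem <- function(x, ...) {
  cat("Linear mixed-effects index model (", x$n_obs, " trials, ",
      x$n_subjects, " subjects; ", x$df_method, " df)\n", sep = "")
  if (!x$converged) cat("NOTE: optimizer did not converge\n")
  if (x$singular) cat("NOTE: singular fit\n")
  print(format(x$terms, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up adjusted p-values with monotonicity enforcement; a test is
#' declared significant when its adjusted p-value is at most `q`.
#'
#' @param p_values Numeric vector of p-values in \[0, 1].
#' @param q FDR level.
#' @return List with `p_adjusted` and logical `reject`.
#' @export
fdr_correct <- function(p_values, q = 0.05) {
  if (length(p_values) == 0) stop("fdr_correct: empty p-value vector")
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("fdr_correct: p-values must lie in [0, 1]")
  }
  adj <- stats::p.adjust(p_values, method = "BH")
  list(p_adjusted = adj, reject = adj <= q)
}

#' Simple slopes of the anxiety moderator within each eCFT condition
#'
#' The slope of the index on standardized trait anxiety evaluated within
#' each condition, obtained as linear combinations of the fixed-effect
#' estimates and their covariance, with two-sided p-values on the
#' approximate (Satterthwaite or Kenward-Roger) degrees of freedom of each
#' combination.
#'
#' @param x A fitted `cftnps_lmem` object.
#' @param moderator Name of the continuous moderator column.
#' @param by Name of the factor within whose levels slopes are evaluated.
#' @return Data frame: `condition`, `slope`, `se`, `df`, `t`, `p`,
#'   `lower`, `upper` (95% CI).
#' @export
simple_slopes <- function(x, moderator = "anxiety_z", by = "condition") {
  stopifnot(inherits(x, "cftnps_lmem"))
  if (!any(grepl(moderator, x$terms$term))) {
    stop("simple_slopes: moderator term '", moderator, "' absent from model")
  }
  tr <- suppressMessages(emmeans::emtrends(
    x$fit, specs = stats::as.formula(paste0("~", by)), var = moderator,
    lmer.df = x$df_method
  ))
  s <- summary(tr, infer = c(TRUE, TRUE))
  data.frame(
    condition = as.character(s[[by]]),
    slope = s[[paste0(moderator, ".trend")]],
    se = s$SE, df = s$df, t = s$t.ratio, p = s$p.value,
    lower = s$lower.CL, upper = s$upper.CL,
    stringsAsFactors = FALSE
  )
}

#' Fit the moderation model across all retained ROIs with FDR correction
#'
#' One mixed model per ROI per index kind; p-values are FDR-adjusted
#' within each fixed-effect term family across ROIs (separately per index
#' kind), matching a reporting scheme in which every printed P is paired
#' with a P_FDR from its own term's sweep. Per-ROI failures are recorded
#' and the sweep continues; ROI ordering is deterministic (sorted labels).
#'
#' @param index_table Index records covering the ROIs to model.
#' @param roi_labels ROI labels to fit (default: all in the table, sorted).
#' @param index_kinds Index kinds to fit (default: all in the table).
#' @param q FDR level for the rejection flag.
#' @param ... Passed to [fit_index_lmem()].
#' @return List: `results` (long data frame of terms with `p_fdr` and
#'   `significant`), `slopes` (simple slopes per ROI x kind), `fits`
#'   (named list of `cftnps_lmem`), `failures` (data frame of ROI x kind
#'   error messages).
#' @export
run_roi_sweep <- function(index_table, roi_labels = NULL, index_kinds = NULL,
                          q = 0.05, ...) {
  if (is.null(roi_labels)) roi_labels <- sort(unique(index_table$roi_label))
  if (is.null(index_kinds)) index_kinds <- unique(index_table$index_kind)
  res <- list(); slp <- list(); fits <- list(); fail <- list()
  for (kind in index_kinds) {
    for (roi in sort(roi_labels)) {
      d <- index_table[index_table$roi_label == roi &
                         index_table$index_kind == kind, , drop = FALSE]
      key <- paste(kind, roi, sep = ":")
      out <- tryCatch({
        f <- fit_index_lmem(d, ...)
        fits[[key]] <- f
        res[[key]] <- cbind(roi_label = roi, index_kind = kind, f$terms,
                            converged = f$converged, singular = f$singular)
        slp[[key]] <- cbind(roi_label = roi, index_kind = kind,
                            simple_slopes(f))
        NULL
      }, error = function(e) conditionMessage(e))
      if (!is.null(out)) {
        fail[[key]] <- data.frame(roi_label = roi, index_kind = kind,
                                  error = out, stringsAsFactors = FALSE)
      }
    }
  }
  results <- do.call(rbind, res)
  if (!is.null(results)) {
    rownames(results) <- NULL
    grp <- paste(results$index_kind, results$term)
    results$p_fdr <- stats::ave(results$p, grp,
                                FUN = function(p) fdr_correct(p, q)$p_adjusted)
    results$significant <- results$p_fdr <= q
  }
  slopes <- do.call(rbind, slp)
  if (!is.null(slopes)) rownames(slopes) <- NULL
  list(results = results, slopes = slopes, fits = fits,
       failures = do.call(rbind, fail))
}
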