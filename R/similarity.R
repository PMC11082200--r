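#' Fisher z-transform of a correlation coefficient
#'
#' Applies the variance-stabilizing transform \eqn{z = \mathrm{arctanh}(r)}
#' used to put Pearson pattern correlations on an additive scale before
#' averaging or differencing. Correlations with \eqn{|r|} at (or numerically
#' above) 1 are clipped to \code{1 - 1e-7} so the transform stays finite.
#'
#' @param r Numeric vector of correlations in \code{[-1, 1]}.
#' @param clip Magnitude at which \code{|r|} is clipped before arctanh.
#' @return Numeric vector of Fisher-z values; \code{NA} propagates.
#' @examples
#' fisher_z(0.5)
#' fisher_z(c(-0.3, 0, 0.3))
#' @export
fisher_z <- function(r, clip = 1 - 1e-7) {
  ok <- !is.na(r)
  if (any(abs(r[ok]) > 1 + 1e-12)) {
    stop("fisher_z: correlation outside [-1, 1]")
  }
  r[ok] <- pmin(pmax(r[ok], -clip), clip)
  atanh(r)
}

#' Neural pattern similarity between two multi-voxel patterns
#'
#' The similarity between two activity patterns is their Fisher
#' z-transformed Pearson correlation across voxels. A zero-variance
#' (constant) pattern has no defined correlation; the value is returned as
#' \code{NA} so the caller can drop and log the record rather than impute.
#'
#' @param a,b Numeric vectors of equal length (>= 2), one value per voxel.
#' @return A single Fisher-z value, or \code{NA_real_} if either pattern has
#'   zero variance.
#' @seealso [fisher_z()], [recall_cft_shift_raw()], [cft_cft_similarity()]
#' @export
nps_correlation <- function(a, b) {
  if (length(a) != length(b)) stop("nps_correlation: patterns differ in length")
  if (length(a) < 2) stop("nps_correlation: need at least 2 voxels")
  if (anyNA(a) || anyNA(b)) return(NA_real_)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  fisher_z(stats::cor(a, b))
}

#' Raw Recall-CFT similarity shift index for one trial
#'
#' Quantifies how much a region's counterfactual-simulation pattern diverged
#' from (negative values) or converged toward (positive values) the pattern
#' of the original memory as the simulation unfolded:
#' \deqn{z(r(\mathrm{Recall}_{4-8s}, \mathrm{CFT}_{4-8s})) -
#'       z(r(\mathrm{Recall}_{4-8s}, \mathrm{CFT}_{0-4s}))}
#' Only the middle recall window (4-8 s) represents the memory: similarity
#' involving the late recall window (8-12 s) and the early CFT window is
#' inflated by BOLD temporal autocorrelation across the short jittered gap,
#' and the late CFT window (8-12 s) is separated from recall by almost twice
#' the interval of the early window, so neither enters the index.
#'
#' @param recall_w4_8 Pattern of the recall epoch, 4-8 s window.
#' @param cft_w0_4 Pattern of the CFT epoch, 0-4 s window.
#' @param cft_w4_8 Pattern of the CFT epoch, 4-8 s window.
#' @return Difference of the two Fisher-z similarities (\code{NA} if any
#'   constituent correlation is undefined).
#' @export
recall_cft_shift_raw <- function(recall_w4_8, cft_w0_4, cft_w4_8) {
  nps_correlation(recall_w4_8, cft_w4_8) - nps_correlation(recall_w4_8, cft_w0_4)
}

#' CFT-CFT similarity index for one trial
#'
#' Mean Fisher-z pattern similarity between one counterfactual simulation
#' (its 4-8 s window pattern) and every other simulation of the same
#' condition acquired in a *different* run:
#' \deqn{\frac{1}{m}\sum_{j \ne x} z(r(\mathrm{CFT}_x, \mathrm{CFT}_j))}
#' where \eqn{m} counts same-condition, different-run instances. Pairs from
#' the focal run are excluded to circumvent similarity inflated by
#' within-run BOLD autocorrelation. High values indicate a generalized
#' representation shared across simulations of that type; low values
#' indicate trial-specific content.
#'
#' @param focal Pattern vector of the focal CFT (4-8 s window).
#' @param others A list of candidate comparison instances, each a list with
#'   elements \code{pattern}, \code{run_id}, \code{condition}.
#' @param focal_run Run identifier of the focal trial.
#' @param focal_condition Condition (\code{"upward"} or \code{"downward"}) of
#'   the focal trial.
#' @return The mean Fisher-z similarity with attribute \code{"m"} (number of
#'   pairs averaged). \code{NA_real_} with \code{m = 0} when the same-run
#'   exclusion exhausts the comparison set; \code{NA} pairs (undefined
#'   correlations) are dropped from the average.
#' @export
cft_cft_similarity <- function(focal, others, focal_run, focal_condition) {
  keep <- vapply(
    others,
    function(o) identical(o$condition, focal_condition) && !identical(o$run_id, focal_run),
    logical(1)
  )
  zs <- vapply(others[keep], function(o) nps_correlation(focal, o$pattern), numeric(1))
  zs <- zs[!is.na(zs)]
  m <- length(zs)
  out <- if (m == 0) NA_real_ else mean(zs)
  attr(out, "m") <- m
  out
}

#' Remove task-interval and previous-trial effects from raw shift indices
#'
#' The raw Recall-CFT shift index carries nuisance structure: the jittered
#' recall-to-CFT interval (1, 2, or 3 s) modulates autocorrelation-driven
#' similarity, and the condition of the previous trial can leave lasting
#' pattern effects. Both are estimated by an ordinary least-squares
#' regression of the raw index on the two categorical nuisance factors --
#' fitted once per ROI, pooling all subjects' trials -- and removed. The
#' grand mean is added back to the residuals so that downstream intercept
#' tests still estimate the mean shift.
#'
#' @param records Data frame of index records with \code{index_kind ==
#'   "recall_cft_shift_raw"}; must contain columns \code{value},
#'   \code{roi_label}, \code{jitter_s}, \code{prev_condition}.
#' @return The same records with \code{value} replaced by the adjusted index
#'   and \code{index_kind} set to \code{"recall_cft_shift_adjusted"}.
#' @details Nuisance levels with zero observations in an ROI are dropped
#'   from that ROI's design (with a message). Rows with \code{NA} values are
#'   passed through unchanged.
#' @export
residualize_shift <- function(records) {
  stopifnot(is.data.frame(records))
  if (!all(records$index_kind == "recall_cft_shift_raw")) {
    stop("residualize_shift: expected records of kind 'recall_cft_shift_raw'")
  }
  out <- records
  for (roi in unique(records$roi_label)) {
    idx <- which(records$roi_label == roi & !is.na(records$value))
    if (length(idx) == 0L) next
    d <- records[idx, , drop = FALSE]
    jit <- factor(d$jitter_s)
    prev <- factor(d$prev_condition)
    dropped <- c(
      setdiff(c("1", "2", "3"), levels(jit)),
      setdiff(c("upward", "downward", "none", "no_previous"), levels(prev))
    )
    if (length(dropped) > 0) {
      message("residualize_shift: ROI ", roi, ": empty nuisance level(s) dropped: ",
              paste(dropped, collapse = ", "))
    }
    # guard against single-level factors (lm() would error)
    form <- if (nlevels(jit) > 1 && nlevels(prev) > 1) {
      d$value ~ jit + prev
    } else if (nlevels(jit) > 1) {
      d$value ~ jit
    } else if (nlevels(prev) > 1) {
      d$value ~ prev
    } else {
      d$value ~ 1
    }
    fit <- stats::lm(form)
    out$value[idx] <- stats::residuals(fit) + mean(d$value)
  }
  out$index_kind <- "recall_cft_shift_adjusted"
  out
}
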