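#' Double-gamma haemodynamic response function
#'
#' Conventional SPM-style shape: response gamma peaking at 6 s, undershoot
#' gamma peaking at 16 s, undershoot scaled by 1/6, both with unit
#' dispersion. Used to convolve nuisance event regressors (other trials,
#' filler task, button presses); focal epochs are modelled with an FIR basis
#' instead.
#'
#' @param t Time grid in seconds (t >= 0).
#' @param peak,undershoot Peak times (s) of the two gamma components.
#' @param ratio Response-to-undershoot amplitude ratio.
#' @return HRF values on \code{t}, scaled to unit peak.
#' @keywords internal
double_gamma_hrf <- function(t, peak = 6, undershoot = 16, ratio = 6) {
  # shape a, rate b with mode (a-1)/b = peak and unit dispersion (b = 1)
  h <- stats::dgamma(t, shape = peak + 1, rate = 1) -
    stats::dgamma(t, shape = undershoot + 1, rate = 1) / ratio
  h / max(h)
}

# Convolve a set of event (onset, duration, amplitude) triplets with the
# double-gamma HRF on a fine grid and sample at TR acquisition times.
# Returns a matrix with columns: convolved regressor and its temporal
# derivative (finite difference of the HRF), both sampled at n_tr TRs.
convolve_events <- function(onsets, durations, tr, n_tr, dt = 0.1,
                            amplitudes = rep(1, length(onsets))) {
  total <- n_tr * tr
  n_fine <- ceiling(total / dt) + 1L
  stick <- numeric(n_fine)
  for (i in seq_along(onsets)) {
    a <- floor(onsets[i] / dt) + 1L
    b <- min(n_fine, ceiling((onsets[i] + max(durations[i], dt)) / dt))
    if (a <= n_fine) stick[a:b] <- stick[a:b] + amplitudes[i]
  }
  tgrid <- seq(0, 32, by = dt)
  h <- double_gamma_hrf(tgrid)
  dh <- c(diff(h) / dt, 0)
  conv_full <- function(k) {
    v <- stats::convolve(stick, rev(k), type = "open")[seq_len(n_fine)] * dt
    # sample at acquisition times t = (0:(n_tr-1)) * tr
    v[pmin(n_fine, floor((0:(n_tr - 1)) * tr / dt) + 1L)]
  }
  cbind(main = conv_full(h), deriv = conv_full(dh))
}

# 0-based TR indices covering one 12-s epoch as three 2-TR FIR windows.
# Onsets are snapped to the nearest TR boundary at or after the onset (the
# jittered 1 s / 3 s gaps misalign CFT onsets by half a TR; snapping keeps
# the 2-TR windows well defined, and the interval residualization absorbs
# the induced interval effects).
epoch_tr_windows <- function(onset, tr, n_windows = 3L, trs_per_window = 2L) {
  start0 <- as.integer(ceiling(onset / tr - 1e-9))
  lapply(seq_len(n_windows) - 1L, function(w) {
    start0 + w * trs_per_window + seq_len(trs_per_window) - 1L
  })
}
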