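#' Process raw EMG into a linear envelope
#'
#' The standard surface-EMG chain, in order: demean, high-pass filter
#' (second-order Butterworth, 20 Hz cut-off), full-wave rectify, low-pass
#' filter (second-order Butterworth, 6 Hz cut-off). Filter undershoot is
#' clamped at zero, since a negative envelope is non-physiological.
#'
#' @param x raw EMG signal, mV, uniformly sampled.
#' @param fs sampling rate, Hz (>= 100).
#' @param hp_cutoff,lp_cutoff high-/low-pass cut-off frequencies, Hz.
#' @return non-negative envelope, same length as `x`.
#' @export
process_emg <- function(x, fs = 1000, hp_cutoff = 20, lp_cutoff = 6) {
  if (fs < 100) stop("sampling rate below 100 Hz")
  x <- x - mean(x)
  x <- highpass_filter(x, fs, hp_cutoff, order = 2)
  x <- abs(x)
  x <- lowpass_filter(x, fs, lp_cutoff, order = 2)
  pmax(x, 0)
}

#' Per-stride maxima of an envelope
#'
#' @param envelope envelope series.
#' @param time sample times, s.
#' @param strikes heel-strike times bounding the strides, s.
#' @return numeric vector, one maximum per stride.
#' @export
stride_maxima <- function(envelope, time, strikes) {
  if (length(strikes) < 2) stop("need at least one stride")
  vapply(seq_len(length(strikes) - 1), function(k) {
    idx <- time >= strikes[k] & time < strikes[k + 1]
    if (!any(idx)) stop("stride window contains no samples")
    max(envelope[idx])
  }, numeric(1))
}

#' Normalize an envelope to baseline-trial stride maxima
#'
#' The normalization denominator is the mean over baseline strides of the
#' per-stride envelope maximum, computed per muscle, subject and session
#' from that session's baseline walking trial.
#'
#' @param envelope envelope series (same units as the baseline envelope).
#' @param baseline_maxima per-stride maxima of the baseline-trial envelope
#'   (at least 3 strides).
#' @return unitless normalized envelope, with the denominator stored in
#'   attribute `"baseline_max"`. A non-positive denominator flags the channel
#'   invalid (attribute `"valid" = FALSE`, envelope all `NA`) with a warning.
#' @export
normalize_emg <- function(envelope, baseline_maxima) {
  if (length(baseline_maxima) < 3) stop("need at least 3 baseline strides")
  denom <- mean(baseline_maxima)
  if (!is.finite(denom) || denom <= 0) {
    warning("zero baseline maximum: channel flagged invalid")
    out <- rep(NA_real_, length(envelope))
    attr(out, "baseline_max") <- denom
    attr(out, "valid") <- FALSE
    return(out)
  }
  out <- envelope / denom
  attr(out, "baseline_max") <- denom
  attr(out, "valid") <- TRUE
  out
}

#' Integrated EMG over a stride
#'
#' Trapezoidal integral of the normalized envelope over
#' `[strike, next strike)`.
#'
#' @param envelope normalized envelope series.
#' @param time sample times, s.
#' @param t0,t1 stride window bounds, s.
#' @return unitless-times-seconds integral.
#' @export
iemg <- function(envelope, time, t0, t1) {
  trapz_window(time, as.numeric(envelope), t0, t1)
}

#' Metabolic power from gas exchange rates
#'
#' `P = 16.58 * vo2 + 4.51 * vco2` watts, with rates in mL/s — the standard
#' indirect-calorimetry energy equivalents (Brockway coefficients).
#'
#' @param vo2 oxygen consumption rate, mL/s.
#' @param vco2 carbon dioxide production rate, mL/s.
#' @return metabolic power, W.
#' @export
metabolic_power <- function(vo2, vco2) {
  if (any(vo2 < 0) || any(vco2 < 0)) stop("gas exchange rates must be >= 0")
  16.58 * vo2 + 4.51 * vco2
}

#' Net metabolic rate of a walking trial
#'
#' Gross rate is the mean metabolic power over the final `window` seconds of
#' the walking trial divided by body mass; the net rate subtracts the
#' session's standing resting rate (same mass throughout, so the order of
#' subtraction and normalization is immaterial).
#'
#' @param walking data frame of breath-averaged gas rates: `time_s`,
#'   `vo2_ml_s`, `vco2_ml_s`.
#' @param resting resting (quiet standing) gas series, same columns.
#' @param mass body mass including the prosthesis, kg.
#' @param window averaging window at the end of the trial, s (default 120).
#' @return list with `gross`, `resting`, `net` (W/kg) and `window` (s).
#' @export
net_metabolic_rate <- function(walking, resting, mass, window = 120) {
  if (mass <= 0) stop("mass must be positive")
  span <- max(walking$time_s) - min(walking$time_s)
  if (span < window) stop("trial shorter than the averaging window")
  keep <- walking$time_s >= max(walking$time_s) - window
  gross <- mean(metabolic_power(walking$vo2_ml_s[keep],
                                walking$vco2_ml_s[keep])) / mass
  rest <- mean(metabolic_power(resting$vo2_ml_s, resting$vco2_ml_s)) / mass
  list(gross = gross, resting = rest, net = gross - rest, window = window)
}
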