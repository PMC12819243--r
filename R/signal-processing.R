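#' Zero-phase Butterworth low-pass filter
#'
#' Forward-backward (zero-phase) filtering with the per-pass order halved so
#' the net asymptotic rolloff matches the stated order, and the per-pass
#' cut-off widened by the standard dual-pass correction factor
#' `(2^(1/2) - 1)^(-1/(2 n))` so the net response still passes -3 dB at the
#' stated cut-off — the textbook convention for gait signal processing.
#'
#' @param x uniformly sampled signal (vector or matrix; columns filtered
#'   independently).
#' @param fs sampling rate, Hz.
#' @param cutoff cut-off frequency, Hz; must be below the Nyquist rate.
#' @param order net filter order, 2 or 4.
#' @return filtered signal, same shape as `x`.
#' @export
lowpass_filter <- function(x, fs, cutoff, order = 4) {
  if (!order %in% c(2, 4)) stop("order must be 2 or 4")
  if (cutoff >= fs / 2) stop("cutoff must be below the Nyquist frequency")
  fc <- min(cutoff * dual_pass_factor(order / 2), 0.99 * fs / 2)
  bf <- signal::butter(order / 2, fc / (fs / 2), type = "low")
  apply_filtfilt(x, bf, pad = ceiling(6 * fs / cutoff))
}

highpass_filter <- function(x, fs, cutoff, order = 2) {
  if (!order %in% c(2, 4)) stop("order must be 2 or 4")
  if (cutoff >= fs / 2) stop("cutoff must be below the Nyquist frequency")
  fc <- cutoff / dual_pass_factor(order / 2)
  bf <- signal::butter(order / 2, fc / (fs / 2), type = "high")
  apply_filtfilt(x, bf, pad = ceiling(6 * fs / cutoff))
}

# cut-off widening for one pass of a dual-pass (zero-phase) Butterworth
dual_pass_factor <- function(pass_order) {
  (2^(1 / 2) - 1)^(-1 / (2 * pass_order))
}

# forward-backward filtering with odd-reflection end padding, so start-up
# transients from zero filter state decay inside the discarded pads
apply_filtfilt <- function(x, bf, pad) {
  one <- function(v) {
    n <- length(v)
    np <- min(pad, n - 1)
    pre <- 2 * v[1] - v[(np + 1):2]
    post <- 2 * v[n] - v[(n - 1):(n - np)]
    y <- signal::filtfilt(bf, c(pre, v, post))
    y[(np + 1):(np + n)]
  }
  if (is.matrix(x) || is.data.frame(x)) {
    out <- as.matrix(x)
    for (j in seq_len(ncol(out))) out[, j] <- one(out[, j])
    out
  } else {
    one(x)
  }
}

# trapezoidal integral of y(t) on its sample grid
trapz <- function(t, y) {
  n <- length(t)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(t))
}

# running trapezoidal integral, same length as input, starting at 0
cumtrapz <- function(t, y) {
  n <- length(t)
  c(0, cumsum((y[-1] + y[-n]) / 2 * diff(t)))
}

# linear interpolation of a (possibly multi-column) series at times tq
interp_series <- function(t, y, tq) {
  if (is.matrix(y) || is.data.frame(y)) {
    y <- as.matrix(y)
    out <- vapply(seq_len(ncol(y)), function(j) {
      stats::approx(t, y[, j], xout = tq, rule = 1)$y
    }, numeric(length(tq)))
    matrix(out, nrow = length(tq), dimnames = list(NULL, colnames(y)))
  } else {
    stats::approx(t, y, xout = tq, rule = 1)$y
  }
}

# trapezoidal integral of y over [t0, t1] with linearly interpolated,
# fractional-sample endpoints
trapz_window <- function(t, y, t0, t1) {
  if (t1 <= t0) stop("empty integration window")
  inside <- which(t > t0 & t < t1)
  tt <- c(t0, t[inside], t1)
  yy <- c(interp_series(t, y, t0), y[inside], interp_series(t, y, t1))
  trapz(tt, yy)
}
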