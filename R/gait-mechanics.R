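#' Detect gait events from vertical ground reaction forces
#'
#' Heel strike is the upward crossing of the force threshold and toe-off the
#' downward crossing (50 N by convention). Detection is debounced: gaps
#' shorter than `min_gap` inside a stance are bridged, and stance phases
#' shorter than `debounce` are discarded. Crossing times are refined by
#' linear interpolation between samples, so events are not snapped to the
#' sample grid.
#'
#' @param grf_left,grf_right vertical GRF per leg, N, on a common uniform
#'   time base.
#' @param time sample times, s.
#' @param threshold crossing threshold, N (default 50).
#' @param debounce minimum stance duration, s.
#' @param min_gap maximum sub-threshold gap bridged within a stance, s.
#' @return object of class `gait_events`: list with per-leg data frames
#'   (`strike`, `toeoff` times, s) and `double_support` (windows from a
#'   leading-leg strike to the trailing-leg toe-off, labeled by leading leg).
#' @export
detect_events <- function(grf_left, grf_right, time, threshold = 50,
                          debounce = 0.2, min_gap = 0.05) {
  if (threshold <= 0) stop("threshold must be positive")
  legs <- list(left = leg_events(grf_left, time, threshold, debounce, min_gap),
               right = leg_events(grf_right, time, threshold, debounce,
                                  min_gap))
  if (nrow(legs$left) == 0 && nrow(legs$right) == 0) {
    warning("no threshold crossings: empty event set")
  }
  ds <- double_support_windows(legs)
  structure(list(left = legs$left, right = legs$right, double_support = ds),
            class = "gait_events")
}

leg_events <- function(f, time, threshold, debounce, min_gap) {
  above <- f > threshold
  if (!any(above)) {
    return(data.frame(strike = numeric(0), toeoff = numeric(0)))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  # bridge short sub-threshold gaps between stances
  dt <- time[2] - time[1]
  keep_gap <- r$values == FALSE & r$lengths * dt < min_gap
  keep_gap[1] <- FALSE
  keep_gap[length(keep_gap)] <- FALSE
  for (k in which(keep_gap)) above[starts[k]:ends[k]] <- TRUE
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1

  strike <- numeric(0)
  toeoff <- numeric(0)
  for (k in which(r$values)) {
    i0 <- starts[k]
    i1 <- ends[k]
    if ((i1 - i0 + 1) * dt < debounce) next
    # stances touching the record edges are incomplete and dropped
    if (i0 == 1 || i1 == length(f)) next
    strike <- c(strike,
                cross_time(time[i0 - 1], time[i0], f[i0 - 1], f[i0],
                           threshold))
    toeoff <- c(toeoff,
                cross_time(time[i1], time[i1 + 1], f[i1], f[i1 + 1],
                           threshold))
  }
  data.frame(strike = strike, toeoff = toeoff)
}

cross_time <- function(t0, t1, f0, f1, threshold) {
  if (f1 == f0) return(t0)
  t0 + (threshold - f0) / (f1 - f0) * (t1 - t0)
}

double_support_windows <- function(legs) {
  out <- list()
  for (leading in c("left", "right")) {
    trailing <- setdiff(c("left", "right"), leading)
    lead_ev <- legs[[leading]]
    trail_ev <- legs[[trailing]]
    for (i in seq_len(nrow(lead_ev))) {
      s <- lead_ev$strike[i]
      j <- which(trail_ev$strike < s & trail_ev$toeoff > s)
      if (length(j) == 1) {
        out[[length(out) + 1]] <- data.frame(
          start = s, end = trail_ev$toeoff[j], leading = leading,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      leading = character(0), stringsAsFactors = FALSE))
  }
  ds <- do.call(rbind, out)
  ds <- ds[order(ds$start), , drop = FALSE]
  rownames(ds) <- NULL
  ds
}

#' Spatiotemporal gait parameters from events and heel markers
#'
#' Stride time and stance time come from the events; stride length is the
#' product of belt speed and stride time (treadmill convention). Step length
#' is the fore-aft and step width the mediolateral distance between
#' contralateral heel markers, both evaluated at the instant of the
#' leading-leg heel strike with markers linearly interpolated to the event
#' time. Steps are labeled trailing-to-leading side.
#'
#' @param events a `gait_events` object.
#' @param markers data frame: `time_s`, `heel_l_x`, `heel_l_y`, `heel_l_z`,
#'   `heel_r_x`, `heel_r_y`, `heel_r_z` (m; x fore-aft, y mediolateral).
#' @param belt_speed treadmill belt speed, m/s.
#' @return list with `strides` (per leg and stride: `leg`, `stride_time`,
#'   `stride_length`, `stance_time`) and `steps` (per step: `leading`,
#'   `label`, `time`, `step_length`, `step_width`).
#' @export
spatiotemporal <- function(events, markers, belt_speed = 1.25) {
  strides <- list()
  for (leg in c("left", "right")) {
    ev <- events[[leg]]
    if (nrow(ev) < 2) next
    st <- diff(ev$strike)
    strides[[leg]] <- data.frame(
      leg = leg, stride = seq_along(st), stride_time = st,
      stride_length = belt_speed * st,
      stance_time = (ev$toeoff - ev$strike)[seq_along(st)],
      stringsAsFactors = FALSE)
  }
  strides <- if (length(strides)) do.call(rbind, strides) else
    data.frame(leg = character(0), stride = integer(0),
               stride_time = numeric(0), stride_length = numeric(0),
               stance_time = numeric(0))
  rownames(strides) <- NULL

  steps <- list()
  for (leading in c("left", "right")) {
    trailing <- setdiff(c("left", "right"), leading)
    for (s in events[[leading]]$strike) {
      if (s < min(markers$time_s) || s > max(markers$time_s)) {
        stop("heel-strike event outside marker time range")
      }
      lead_xy <- interp_series(markers$time_s,
                               markers[, paste0("heel_", substr(leading, 1, 1),
                                                c("_x", "_y"))], s)
      trail_xy <- interp_series(markers$time_s,
                                markers[, paste0("heel_", substr(trailing, 1, 1),
                                                 c("_x", "_y"))], s)
      steps[[length(steps) + 1]] <- data.frame(
        leading = leading, label = paste0(trailing, "_to_", leading),
        time = s,
        step_length = lead_xy[1] - trail_xy[1],
        step_width = abs(lead_xy[2] - trail_xy[2]),
        stringsAsFactors = FALSE)
    }
  }
  steps <- if (length(steps)) do.call(rbind, steps) else
    data.frame(leading = character(0), label = character(0), time = numeric(0),
               step_length = numeric(0), step_width = numeric(0))
  steps <- steps[order(steps$time), , drop = FALSE]
  rownames(steps) <- NULL
  list(strides = strides, steps = steps)
}

#' Center-of-mass velocity from total ground reaction force
#'
#' Newtonian integration per stride: `v(t) = c + integral of (F - m g zhat)/m`,
#' with the integration constant chosen so the stride-average velocity equals
#' `(belt_speed, 0, 0)` in the belt frame — the steady-state treadmill
#' assumption of the individual-limbs method. Strides are consecutive heel
#' strikes of the reference leg.
#'
#' @param grf_total n-by-3 total (left plus right) GRF matrix, N, columns
#'   x (fore-aft), y (mediolateral), z (vertical).
#' @param time sample times, s.
#' @param mass body mass including the prosthesis, kg.
#' @param stride_times heel-strike times bounding the strides, s.
#' @param belt_speed treadmill belt speed, m/s.
#' @param g gravitational acceleration, m/s^2.
#' @return n-by-3 matrix of COM velocity, m/s; `NA` outside the stride span.
#' @export
com_velocity <- function(grf_total, time, mass, stride_times,
                         belt_speed = 1.25, g = 9.81) {
  if (mass <= 0) stop("mass must be positive")
  if (length(stride_times) < 2) stop("need at least one stride window")
  acc <- sweep(as.matrix(grf_total), 2, c(0, 0, mass * g)) / mass
  v <- matrix(NA_real_, nrow = length(time), ncol = 3,
              dimnames = list(NULL, c("x", "y", "z")))
  target <- c(belt_speed, 0, 0)
  for (k in seq_len(length(stride_times) - 1)) {
    idx <- which(time >= stride_times[k] & time <= stride_times[k + 1])
    if (length(idx) < 2) next
    tt <- time[idx]
    for (j in 1:3) {
      vj <- cumtrapz(tt, acc[idx, j])
      v[idx, j] <- vj - trapz(tt, vj) / (tt[length(tt)] - tt[1]) + target[j]
    }
  }
  v
}

#' Individual-limb step-to-step transition work
#'
#' For each double-support window and leg, the external mechanical power is
#' the dot product of that leg's GRF vector with the COM velocity vector;
#' positive and negative work are the trapezoidal integrals of its positive
#' and negative portions over the window (endpoints linearly interpolated).
#'
#' @param grf_left,grf_right n-by-3 per-leg GRF matrices, N.
#' @param v_com n-by-3 COM velocity matrix from [com_velocity()], m/s.
#' @param time sample times, s.
#' @param events a `gait_events` object (supplies the double-support
#'   windows).
#' @param mass body mass, kg, for the per-kg normalization.
#' @return data frame, one row per window and leg: `window`, `start`, `end`,
#'   `leg`, `role` (`leading`/`trailing`), `work_positive` and
#'   `work_negative` (J), and the same per kg.
#' @export
transition_work <- function(grf_left, grf_right, v_com, time, events, mass) {
  ds <- events$double_support
  if (nrow(ds) == 0) stop("no double-support windows")
  grf <- list(left = as.matrix(grf_left), right = as.matrix(grf_right))
  out <- list()
  for (w in seq_len(nrow(ds))) {
    idx <- which(time >= ds$start[w] & time <= ds$end[w])
    if (length(idx) < 2) stop("empty double-support window")
    # include the bracketing samples used by the endpoint interpolation
    idx_ext <- max(1, min(idx) - 1):min(length(time), max(idx) + 1)
    if (anyNA(v_com[idx_ext, ])) next  # window outside integrated stride span
    for (leg in c("left", "right")) {
      p <- rowSums(grf[[leg]][idx_ext, , drop = FALSE] *
                     v_com[idx_ext, , drop = FALSE])
      wp <- trapz_window(time[idx_ext], pmax(p, 0), ds$start[w], ds$end[w])
      wn <- trapz_window(time[idx_ext], pmin(p, 0), ds$start[w], ds$end[w])
      out[[length(out) + 1]] <- data.frame(
        window = w, start = ds$start[w], end = ds$end[w], leg = leg,
        role = if (leg == ds$leading[w]) "leading" else "trailing",
        work_positive = wp, work_negative = wn,
        work_positive_per_kg = wp / mass, work_negative_per_kg = wn / mass,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) stop("no double-support window inside the stride span")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
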