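#' @title Synthetic raw gait-trial signals
#' @description
#' Generates per-trial raw signal bundles — per-leg 3-axis ground reaction
#' forces (1000 Hz), heel-marker trajectories (100 Hz), joint-angle series
#' (100 Hz), surface EMG (1000 Hz) and breath-averaged gas exchange — for a
#' subject walking at 1.25 m/s under a given prosthesis configuration, with
#' the generating ground truth stored alongside.
#'
#' The vertical GRF stance template is a sum of two Gaussian bumps scaled to
#' body weight (peaks near 1.05-1.15 BW) on a smooth edge window, plus a
#' midstance filler solved so each leg's stride-averaged vertical force
#' equals half body weight (steady-gait impulse balance). Consecutive
#' contralateral stances overlap by roughly 12% of the stride (double
#' support). The fore-aft GRF is braking-then-propulsive; the affected leg's
#' propulsive amplitude is calibrated by a secant search so the trailing-leg
#' positive transition work hits its target, which rises by 0.025 J/kg per
#' battery power step. Stiffness categories shift the prosthetic heel and
#' forefoot rotational stiffness by 0.01 and 0.12 kN-m/rad per category in
#' the ankle angle-trajectory model.
#' @name synthetic_signals
NULL

gaussb <- function(x, center, sd) exp(-((x - center)^2) / (2 * sd^2))

edge_window <- function(phi, ramp = 0.06) {
  w <- pmax(pmin(phi / ramp, (1 - phi) / ramp, 1), 0)
  sin(w * pi / 2)^2
}

# stance-phase vertical GRF template in body-weight units
make_fz_template <- function(p1, p2, stride_T, stance_T,
                             c1 = 0.27, c2 = 0.73, sd = 0.15) {
  base <- function(phi) {
    edge_window(phi) * (p1 * gaussb(phi, c1, sd) + p2 * gaussb(phi, c2, sd))
  }
  fill <- function(phi) edge_window(phi) * sin(pi * phi)^8
  grid <- seq(0, 1, length.out = 2001)
  # per-leg stride-average force = BW/2  =>  integral over stance phase
  target <- stride_T / (2 * stance_T)
  cfill <- (target - mean(base(grid))) / mean(fill(grid))
  function(phi) base(phi) + cfill * fill(phi)
}

# braking-then-propulsive fore-aft template, body-weight units
make_fx_template <- function(amp_brake, amp_prop) {
  function(phi) {
    a <- ifelse(phi < 0.5, amp_brake, amp_prop)
    edge_window(phi) * a * (-sin(2 * pi * phi))
  }
}

# mediolateral template, positive toward the midline, body-weight units
fml_template <- function(phi) {
  edge_window(phi) * (0.05 * sin(pi * phi) - 0.03 * sin(2 * pi * phi))
}

# evaluate a stance template on a time grid for a leg striking at t0 + k*T
leg_series <- function(time, t0, stride_T, stance_T, template) {
  ph <- ((time - t0) %% stride_T) / stance_T
  out <- numeric(length(time))
  on <- ph < 1
  out[on] <- template(ph[on])
  out
}

# solve the stance-phase fractions where the clean template crosses `thr`
template_crossings <- function(template, thr) {
  up <- stats::uniroot(function(p) template(p) - thr, c(1e-6, 0.25))$root
  down <- stats::uniroot(function(p) template(p) - thr, c(0.75, 1 - 1e-6))$root
  c(up = up, down = down)
}

# muscle envelope shapes: bursts (center, width, relative height) on the
# leg's stride phase, plus a small tonic floor
muscle_bursts <- list(
  biceps_femoris = list(c(0.05, 0.08, 1), c(0.92, 0.06, 0.6), amp = 0.5),
  gluteus_maximus = list(c(0.08, 0.09, 1), amp = 0.4),
  vastus_lateralis = list(c(0.12, 0.08, 1), amp = 0.6),
  rectus_femoris = list(c(0.15, 0.10, 1), c(0.70, 0.08, 0.4), amp = 0.45),
  lateral_gastrocnemius = list(c(0.45, 0.10, 1), amp = 0.7),
  soleus = list(c(0.48, 0.10, 1), amp = 0.8),
  tibialis_anterior = list(c(0.03, 0.06, 1), c(0.80, 0.15, 0.5), amp = 0.5))

muscle_envelope <- function(psi, muscle, amp_scale = 1) {
  spec <- muscle_bursts[[muscle]]
  amp <- spec$amp * amp_scale
  bursts <- spec[names(spec) == ""]
  v <- rep(0.05, length(psi))
  for (b in bursts) v <- v + b[3] * gaussb(psi, b[1], b[2])
  amp * v
}

# joint-angle stance waveforms (degrees, stride phase psi in [0,1)).
# The prosthetic ankle follows a compliance model: peak angles are the peak
# heel/forefoot moments divided by the rotational stiffnesses, which shift
# by 0.01 (heel) and 0.12 (forefoot) kN-m/rad per stiffness category.
angle_waveforms <- function(side_is_affected, mass, stiffness, power,
                            jit = function() 1) {
  k_heel <- 0.065 + 0.01 * stiffness    # kN-m/rad
  k_fore <- 0.45 + 0.12 * stiffness
  m_heel <- 0.08e-3 * mass              # kN-m peak heel moment
  m_fore <- 1.2e-3 * mass
  rad2deg <- 180 / pi
  if (side_is_affected) {
    a_pf1 <- m_heel / k_heel * rad2deg
    a_df <- m_fore / k_fore * rad2deg
    a_pf2 <- 12 + 1.5 * power
    inv <- c(2, 1.5)
  } else {
    a_pf1 <- 6; a_df <- 12; a_pf2 <- 18
    inv <- c(8, 4)
  }
  list(
    ankle_sagittal = function(psi) jit() *
      (-a_pf1 * gaussb(psi, 0.05, 0.05) + a_df * gaussb(psi, 0.32, 0.14) -
         a_pf2 * gaussb(psi, 0.60, 0.07)),
    ankle_frontal = function(psi) jit() *
      (inv[1] * gaussb(psi, 0.25, 0.12) - inv[2] * gaussb(psi, 0.55, 0.12)),
    knee = function(psi) jit() *
      (18 * gaussb(psi, 0.15, 0.08) - 2 * gaussb(psi, 0.42, 0.08) +
         60 * gaussb(psi, 0.75, 0.10)),
    hip_sagittal = function(psi) jit() * (25 * cos(2 * pi * psi) + 3),
    hip_frontal = function(psi) jit() *
      (8 * gaussb(psi, 0.15, 0.10) - 5 * gaussb(psi, 0.60, 0.15)),
    hip_transverse = function(psi) jit() * (6 * sin(2 * pi * psi + 0.4)))
}

#' Generate one synthetic raw gait trial
#'
#' @param subject one-row subject profile (see [generate_cohort()]).
#' @param config one-row configuration (see [prosthesis_configs()]).
#' @param duration motion-capture duration, s; must cover at least 4 strides.
#'   Gas exchange is emitted for the full `gas_duration` walking trial.
#' @param seed integer RNG seed; the trial is a pure function of the
#'   arguments.
#' @param belt_speed treadmill speed, m/s.
#' @param fs,fs_marker GRF/EMG and marker/angle sampling rates, Hz.
#' @param gas_duration walking-trial length for gas exchange, s.
#' @param noise_grf,noise_marker measurement noise SDs (N, m).
#' @return object of class `raw_trial`: signal tables (`grf`, `markers`,
#'   `angles`, `emg`, `gases`, `gases_resting`), metadata and `true_values`
#'   (events, spatiotemporal parameters, transition work per kg, COM
#'   velocity, GRF/angle peaks, net metabolic rate).
#' @export
generate_trial_signals <- function(subject, config, duration = 30, seed = 1L,
                                   belt_speed = 1.25, fs = 1000,
                                   fs_marker = 100, gas_duration = 300,
                                   noise_grf = 1, noise_marker = 2e-4) {
  set.seed(seed)
  stride_T <- 1.12 * sqrt(subject$height / 1.75) + rnorm(1, 0, 0.01)
  if (duration < 4 * stride_T) {
    stop("duration must cover at least 4 stride periods")
  }
  stance_T <- 0.62 * stride_T
  mass <- subject$mass
  bw <- mass * 9.81
  affected <- subject$affected_side            # "left" or "right"
  unaffected <- setdiff(c("left", "right"), affected)
  t0 <- list()
  t0[[affected]] <- 0.35
  delta <- 0.5 + rnorm(1, 0, 0.004)            # step-timing asymmetry
  t0[[unaffected]] <- 0.35 + delta * stride_T

  time <- seq(0, duration, by = 1 / fs)
  n <- length(time)

  # --- vertical GRF ---
  p1 <- c(1.10, 1.10) + rnorm(2, 0, 0.01)
  p2 <- c(1.05 + 0.005 * config$power, 1.07) + rnorm(2, 0, 0.01)
  fz_tpl <- list()
  fz_tpl[[affected]] <- make_fz_template(p1[1], p2[1], stride_T, stance_T)
  fz_tpl[[unaffected]] <- make_fz_template(p1[2], p2[2], stride_T, stance_T)

  # --- fore-aft GRF: calibrate affected propulsive amplitude so trailing
  #     positive transition work hits its target ---
  work_target <- 0.20 + 0.025 * config$power + 0.005 * (config$stiffness + 1)
  amp_brake <- c(0.17, 0.17) + rnorm(2, 0, 0.005)
  amp_prop_un <- 0.17 + rnorm(1, 0, 0.005)

  clean_grf <- function(amp_prop_aff, tt) {
    tpl_fx <- list()
    tpl_fx[[affected]] <- make_fx_template(amp_brake[1], amp_prop_aff)
    tpl_fx[[unaffected]] <- make_fx_template(amp_brake[2], amp_prop_un)
    out <- list()
    for (leg in c("left", "right")) {
      sgn <- if (leg == "left") -1 else 1   # midline-positive to lab y
      out[[leg]] <- cbind(
        x = bw * leg_series(tt, t0[[leg]], stride_T, stance_T, tpl_fx[[leg]]),
        y = sgn * bw * leg_series(tt, t0[[leg]], stride_T, stance_T,
                                  fml_template),
        z = bw * leg_series(tt, t0[[leg]], stride_T, stance_T, fz_tpl[[leg]]))
    }
    out
  }

  cross <- lapply(c(left = "left", right = "right"), function(leg) {
    template_crossings(fz_tpl[[leg]], 50 / bw)
  })
  events_of <- function(tt_max) {
    evs <- lapply(c(left = "left", right = "right"), function(leg) {
      # pair strike and toe-off by gait cycle so stances stay aligned
      k <- seq(floor(-t0[[leg]] / stride_T) - 1,
               ceiling(tt_max / stride_T) + 1)
      strike <- t0[[leg]] + k * stride_T + cross[[leg]]["up"] * stance_T
      toeoff <- t0[[leg]] + k * stride_T + cross[[leg]]["down"] * stance_T
      keep <- strike >= 0 & toeoff <= tt_max
      data.frame(strike = strike[keep], toeoff = toeoff[keep])
    })
    structure(list(left = evs$left, right = evs$right,
                   double_support = double_support_windows(evs)),
              class = "gait_events")
  }

  trailing_aff_pos_work <- function(amp_prop_aff) {
    tt <- seq(0, 8 * stride_T, by = 1 / fs)
    g <- clean_grf(amp_prop_aff, tt)
    ev <- events_of(max(tt))
    v <- com_velocity(g$left + g$right, tt, mass,
                      ev[[affected]]$strike, belt_speed)
    tw <- transition_work(g$left, g$right, v, tt, ev, mass)
    sel <- tw$leg == affected & tw$role == "trailing"
    mean(tw$work_positive_per_kg[sel])
  }

  # secant solve (work is nearly affine in the propulsive amplitude)
  a0 <- 0.10; a1 <- 0.25
  w0 <- trailing_aff_pos_work(a0); w1 <- trailing_aff_pos_work(a1)
  for (it in 1:2) {
    a2 <- a1 + (work_target - w1) * (a1 - a0) / (w1 - w0)
    a2 <- min(max(a2, 0.02), 0.6)
    a0 <- a1; w0 <- w1
    a1 <- a2; w1 <- trailing_aff_pos_work(a2)
  }
  amp_prop_aff <- a1

  grf_clean <- clean_grf(amp_prop_aff, time)
  events_true <- events_of(duration)

  # --- ground-truth mechanics on the clean signals ---
  v_true <- com_velocity(grf_clean$left + grf_clean$right, time, mass,
                         events_true[[affected]]$strike, belt_speed)
  tw_true <- transition_work(grf_clean$left, grf_clean$right, v_true, time,
                             events_true, mass)
  side_of <- function(leg) ifelse(leg == affected, "affected", "unaffected")
  work_true <- c()
  for (role in c("leading", "trailing")) {
    for (leg in c("left", "right")) {
      sel <- tw_true$leg == leg & tw_true$role == role
      work_true[paste("work", role, side_of(leg), "positive", sep = "_")] <-
        mean(tw_true$work_positive_per_kg[sel])
      work_true[paste("work", role, side_of(leg), "negative", sep = "_")] <-
        abs(mean(tw_true$work_negative_per_kg[sel]))  # stored as magnitude
    }
  }

  # --- heel markers ---
  step_width <- 0.12 + rnorm(1, 0, 0.01)
  d_hs <- rnorm(1, 0, 0.01)   # fore-aft strike-position asymmetry
  x_hs <- list()
  x_hs[[affected]] <- d_hs / 2
  x_hs[[unaffected]] <- -d_hs / 2
  heel_x_fun <- function(leg) {
    x0 <- x_hs[[leg]]
    swing_T <- stride_T - stance_T
    function(tt) {
      ph <- ((tt - t0[[leg]]) %% stride_T)
      s <- pmax((ph - stance_T) / swing_T, 0)
      # quintic Hermite swing: heel speed matches the belt at toe-off and
      # at landing, so the trajectory is C1 at the contact events
      h00 <- 1 - 10 * s^3 + 15 * s^4 - 6 * s^5
      h10 <- s - 6 * s^3 + 8 * s^4 - 3 * s^5
      h01 <- 10 * s^3 - 15 * s^4 + 6 * s^5
      h11 <- -4 * s^3 + 7 * s^4 - 3 * s^5
      toe_x <- x0 - belt_speed * stance_T
      m <- -belt_speed * swing_T
      swing_x <- toe_x * h00 + m * h10 + x0 * h01 + m * h11
      ifelse(ph < stance_T, x0 - belt_speed * ph, swing_x)
    }
  }
  heel_z_fun <- function(leg) {
    function(tt) {
      ph <- ((tt - t0[[leg]]) %% stride_T)
      s <- pmax((ph - stance_T) / (stride_T - stance_T), 0)
      0.03 + 0.10 * sin(pi * s)^2
    }
  }
  y_heel <- c(left = step_width / 2, right = -step_width / 2)
  tm <- seq(0, duration, by = 1 / fs_marker)
  markers <- data.frame(time_s = tm)
  for (leg in c("left", "right")) {
    pre <- paste0("heel_", substr(leg, 1, 1))
    markers[[paste0(pre, "_x")]] <- heel_x_fun(leg)(tm) +
      rnorm(length(tm), 0, noise_marker)
    markers[[paste0(pre, "_y")]] <- y_heel[leg] +
      rnorm(length(tm), 0, noise_marker)
    markers[[paste0(pre, "_z")]] <- heel_z_fun(leg)(tm) +
      rnorm(length(tm), 0, noise_marker)
  }

  # truth step lengths evaluated at the true strike instants
  first_strike <- function(leg) events_true[[leg]]$strike[1]
  sl_at <- function(lead) {
    trail <- setdiff(c("left", "right"), lead)
    s <- first_strike(lead)
    heel_x_fun(lead)(s) - heel_x_fun(trail)(s)
  }
  step_len_u2a <- sl_at(affected)      # unaffected trailing, affected leading
  step_len_a2u <- sl_at(unaffected)

  # --- joint angles (clean waveform + per-trial amplitude jitter) ---
  amp_jit <- function() 1 + rnorm(1, 0, 0.05)
  angles <- data.frame(time_s = tm)
  angle_true <- c()
  peak_dirs <- list(
    ankle_sagittal = c("dorsiflexion", "plantarflexion"),
    ankle_frontal = c("inversion", "eversion"),
    knee = c("flexion", "extension"),
    hip_sagittal = c("flexion", "extension"),
    hip_frontal = c("adduction", "abduction"),
    hip_transverse = c("internal_rotation", "external_rotation"))
  psi_grid <- seq(0, 0.62, length.out = 500)   # stance-phase grid
  for (leg in c("left", "right")) {
    wf <- angle_waveforms(leg == affected, mass, config$stiffness,
                          config$power, amp_jit)
    side <- side_of(leg)
    for (ch in names(wf)) {
      psi <- ((tm - t0[[leg]]) %% stride_T) / stride_T
      angles[[paste0(ch, "_", substr(leg, 1, 1))]] <- wf[[ch]](psi) +
        rnorm(length(tm), 0, 0.2)
      stance_vals <- wf[[ch]](psi_grid)
      dirs <- peak_dirs[[ch]]
      prefix <- sub("_sagittal|_frontal|_transverse", "", ch)
      angle_true[paste("angle", side, prefix, dirs[1], sep = "_")] <-
        max(stance_vals)
      angle_true[paste("angle", side, prefix, dirs[2], sep = "_")] <-
        -min(stance_vals)
    }
  }

  # --- GRF peak truths (clean templates, Newtons) ---
  phg <- seq(0, 1, length.out = 2000)
  grf_true <- c()
  for (leg in c("left", "right")) {
    side <- side_of(leg)
    fz <- fz_tpl[[leg]](phg) * bw
    half <- phg < 0.5
    grf_true[paste0("grf_", side, "_vertical_peak1")] <- max(fz[half])
    grf_true[paste0("grf_", side, "_vertical_peak2")] <- max(fz[!half])
    fx <- make_fx_template(amp_brake[if (leg == affected) 1 else 2],
                           if (leg == affected) amp_prop_aff else
                             amp_prop_un)(phg) * bw
    grf_true[paste0("grf_", side, "_braking")] <- -min(fx)
    grf_true[paste0("grf_", side, "_propulsive")] <- max(fx)
    fml <- fml_template(phg) * bw
    grf_true[paste0("grf_", side, "_medial")] <- max(fml)
    grf_true[paste0("grf_", side, "_lateral")] <- -min(fml)
  }

  # --- EMG ---
  te <- time
  emg <- data.frame(time_s = te)
  emg_channels <- c()
  iemg_true <- c()
  for (side in c("affected", "unaffected")) {
    leg <- if (side == "affected") affected else unaffected
    muscles <- if (side == "affected") muscles_affected else muscles_unaffected
    for (m in muscles) {
      psi <- ((te - t0[[leg]]) %% stride_T) / stride_T
      amp_scale <- 1 + rnorm(1, 0, 0.1)
      env <- muscle_envelope(psi, m, amp_scale)
      col <- paste0(m, "_", substr(leg, 1, 1))
      emg[[col]] <- env * rnorm(length(te))
      emg_channels[col] <- paste0("iemg_", side, "_", m)
      iemg_true[paste0("iemg_", side, "_", m)] <-
        mean(muscle_envelope(seq(0, 1, length.out = 1000), m, amp_scale)) *
        stride_T
    }
  }

  # --- gas exchange (walking trial + quiet standing) ---
  rest_rate <- 1.2 + rnorm(1, 0, 0.1)          # W/kg
  net_target <- 3.4 - 0.08 * config$power + 0.02 * abs(config$stiffness + 1) +
    rnorm(1, 0, 0.05)
  breath_series <- function(total_s, rate_w_kg) {
    bt <- cumsum(3.5 + runif(ceiling(total_s / 2.5), -0.5, 0.5))
    bt <- bt[bt <= total_s]
    p <- rate_w_kg * mass * (1 + rnorm(length(bt), 0, 0.02))
    vo2 <- p / (16.58 + 4.51 * 0.85)
    data.frame(time_s = bt, vo2_ml_s = vo2, vco2_ml_s = 0.85 * vo2)
  }
  gases <- breath_series(gas_duration, net_target + rest_rate)
  gases_resting <- breath_series(gas_duration, rest_rate)

  # --- emitted (noisy) signals ---
  grf <- data.frame(time_s = time,
                    fx_l = grf_clean$left[, "x"], fy_l = grf_clean$left[, "y"],
                    fz_l = grf_clean$left[, "z"],
                    fx_r = grf_clean$right[, "x"],
                    fy_r = grf_clean$right[, "y"],
                    fz_r = grf_clean$right[, "z"])
  for (cl in setdiff(names(grf), "time_s")) {
    grf[[cl]] <- grf[[cl]] + rnorm(n, 0, noise_grf)
  }

  true_values <- c(
    list(stride_time = stride_T, stance_time = stance_T,
         stride_length = belt_speed * stride_T,
         step_length_a2u = step_len_a2u, step_length_u2a = step_len_u2a,
         step_width = step_width,
         events = events_true, com_velocity = v_true,
         net_met_rate = net_target, resting_rate = rest_rate),
    as.list(work_true), as.list(grf_true), as.list(angle_true),
    as.list(iemg_true))

  structure(list(
    trial_id = sprintf("%s_s%+d_p%d", subject$subject_id, config$stiffness,
                       config$power),
    subject = subject, config = config,
    belt_speed = belt_speed, fs = fs, fs_marker = fs_marker,
    duration = duration,
    grf = grf, markers = markers, angles = angles, emg = emg,
    emg_channels = emg_channels,
    gases = gases, gases_resting = gases_resting,
    true_values = true_values), class = "raw_trial")
}

#' @export
print.raw_trial <- function(x, ...) {
  cat(sprintf("raw_trial %s: %.0f s at %g Hz, config (%s stiffness, %s)\n",
              x$trial_id, x$duration, x$fs, x$config$stiffness_label,
              x$config$power_label))
  invisible(x)
}
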