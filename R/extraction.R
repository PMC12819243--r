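#' @title Raw-signal feature extraction
#' @description
#' Runs the full processing chain on a raw trial: GRF and marker low-pass
#' filtering (fourth-order zero-phase Butterworth, 7 Hz), 50 N gait-event
#' detection, spatiotemporal parameters, COM velocity and individual-limb
#' step-to-step transition work, stance-phase GRF and joint-angle peaks, EMG
#' envelopes normalized to the baseline trial and integrated per stride, and
#' net metabolic rate — emitting stride-level values keyed by registry
#' feature names.
#' @name extraction
NULL

angle_channel_dirs <- list(
  ankle_sagittal = c("ankle_dorsiflexion", "ankle_plantarflexion"),
  ankle_frontal = c("ankle_inversion", "ankle_eversion"),
  knee = c("knee_flexion", "knee_extension"),
  hip_sagittal = c("hip_flexion", "hip_extension"),
  hip_frontal = c("hip_adduction", "hip_abduction"),
  hip_transverse = c("hip_internal_rotation", "hip_external_rotation"))

#' Baseline-trial EMG normalization denominators
#'
#' Processes every EMG channel of a baseline walking trial and returns the
#' mean per-stride envelope maximum per channel, keyed by registry feature
#' name.
#'
#' @param trial a `raw_trial` (the subject's baseline condition).
#' @return named numeric vector of denominators.
#' @export
emg_baseline_maxima <- function(trial) {
  ev <- detect_events(trial$grf$fz_l, trial$grf$fz_r, trial$grf$time_s)
  out <- c()
  for (col in names(trial$emg_channels)) {
    leg <- if (endsWith(col, "_l")) "left" else "right"
    strikes <- ev[[leg]]$strike
    env <- process_emg(trial$emg[[col]], trial$fs)
    out[trial$emg_channels[[col]]] <-
      mean(stride_maxima(env, trial$emg$time_s, strikes))
  }
  out
}

#' Extract stride-level feature values from one raw trial
#'
#' @param trial a `raw_trial`.
#' @param emg_baseline named denominators from [emg_baseline_maxima()]
#'   (the trial's own maxima are used when omitted, as for the baseline
#'   trial itself).
#' @return list: `strides` (long data frame `variable`, `stride`, `value`),
#'   `outcome` (net metabolic rate, W/kg), `events`, `metabolic` summary.
#' @export
extract_trial <- function(trial, emg_baseline = NULL) {
  time <- trial$grf$time_s
  fs <- trial$fs
  affected <- trial$subject$affected_side
  side_of <- function(leg) ifelse(leg == affected, "affected", "unaffected")
  mass <- trial$subject$mass

  grf_f <- lapply(list(l = c("fx_l", "fy_l", "fz_l"),
                       r = c("fx_r", "fy_r", "fz_r")), function(cols) {
    lowpass_filter(as.matrix(trial$grf[cols]), fs, 7, order = 4)
  })
  events <- detect_events(trial$grf$fz_l, trial$grf$fz_r, time)

  vals <- list()
  add <- function(variable, value) {
    vals[[length(vals) + 1]] <<- data.frame(
      variable = variable, stride = seq_along(value), value = value,
      stringsAsFactors = FALSE)
  }

  # --- spatiotemporal (markers used unfiltered: the heel trajectory has a
  #     slope corner at contact that low-pass filtering would smear) ---
  spt <- spatiotemporal(events, trial$markers, trial$belt_speed)
  add("spt_stride_length", spt$strides$stride_length)
  for (leg in c("left", "right")) {
    sel <- spt$strides$leg == leg
    add(paste0("spt_stance_time_", side_of(leg)),
        spt$strides$stance_time[sel])
  }
  lab_a2u <- paste0(affected, "_to_",
                    setdiff(c("left", "right"), affected))
  add("spt_step_length_a2u", spt$steps$step_length[spt$steps$label == lab_a2u])
  add("spt_step_length_u2a", spt$steps$step_length[spt$steps$label != lab_a2u])
  add("spt_step_width", spt$steps$step_width)

  # --- transition work (J; mass normalization happens at table stage) ---
  leg_ref <- events[[affected]]$strike
  vcom <- com_velocity(grf_f$l + grf_f$r, time, mass, leg_ref,
                       trial$belt_speed)
  tw <- transition_work(grf_f$l, grf_f$r, vcom, time, events, mass)
  for (role in c("leading", "trailing")) {
    for (leg in c("left", "right")) {
      sel <- tw$leg == leg & tw$role == role
      add(paste("work", role, side_of(leg), "positive", sep = "_"),
          tw$work_positive[sel])
      add(paste("work", role, side_of(leg), "negative", sep = "_"),
          abs(tw$work_negative[sel]))
    }
  }

  # --- GRF stance peaks (N) ---
  for (leg in c("left", "right")) {
    side <- side_of(leg)
    stance <- data.frame(start = events[[leg]]$strike,
                         end = events[[leg]]$toeoff)
    lg <- substr(leg, 1, 1)
    vz <- extract_peaks(grf_f[[lg]][, paste0("fz_", lg)], time, stance,
                        mode = "vertical_grf")
    add(paste0("grf_", side, "_vertical_peak1"), vz$peak1)
    add(paste0("grf_", side, "_vertical_peak2"), vz$peak2)
    fx <- extract_peaks(grf_f[[lg]][, paste0("fx_", lg)], time, stance)
    add(paste0("grf_", side, "_propulsive"), fx$peak_max)
    add(paste0("grf_", side, "_braking"), -fx$peak_min)
    ml_sign <- if (leg == "left") -1 else 1   # midline-positive convention
    fy <- extract_peaks(ml_sign * grf_f[[lg]][, paste0("fy_", lg)], time,
                        stance)
    add(paste0("grf_", side, "_medial"), fy$peak_max)
    add(paste0("grf_", side, "_lateral"), -fy$peak_min)
  }

  # --- joint-angle stance peaks (deg) ---
  ta <- trial$angles$time_s
  ang_cols <- setdiff(names(trial$angles), "time_s")
  angles_f <- trial$angles
  angles_f[ang_cols] <- lowpass_filter(as.matrix(trial$angles[ang_cols]),
                                       trial$fs_marker, 7, order = 4)
  for (leg in c("left", "right")) {
    side <- side_of(leg)
    stance <- data.frame(start = events[[leg]]$strike,
                         end = events[[leg]]$toeoff)
    for (ch in names(angle_channel_dirs)) {
      col <- paste0(ch, "_", substr(leg, 1, 1))
      pk <- extract_peaks(angles_f[[col]], ta, stance)
      dirs <- angle_channel_dirs[[ch]]
      add(paste("angle", side, dirs[1], sep = "_"), pk$peak_max)
      add(paste("angle", side, dirs[2], sep = "_"), -pk$peak_min)
    }
  }

  # --- integrated EMG per stride ---
  if (is.null(emg_baseline)) emg_baseline <- emg_baseline_maxima(trial)
  for (col in names(trial$emg_channels)) {
    feat <- trial$emg_channels[[col]]
    leg <- if (endsWith(col, "_l")) "left" else "right"
    strikes <- events[[leg]]$strike
    env <- process_emg(trial$emg[[col]], fs)
    nenv <- normalize_emg(env, rep(emg_baseline[[feat]], 3))
    if (isFALSE(attr(nenv, "valid"))) next
    vv <- vapply(seq_len(length(strikes) - 1), function(k) {
      iemg(nenv, trial$emg$time_s, strikes[k], strikes[k + 1])
    }, numeric(1))
    add(feat, vv)
  }

  met <- net_metabolic_rate(trial$gases, trial$gases_resting, mass)
  strides <- do.call(rbind, vals)
  strides <- strides[is.finite(strides$value), , drop = FALSE]
  list(strides = strides, outcome = met$net, events = events,
       metabolic = met)
}

#' Build the trial-by-feature table from raw trials
#'
#' Extracts stride-level values from every trial, removes per-stride
#' outliers within subject and variable (3 SD single pass), averages the
#' retained strides per trial, attaches subject and prosthesis features and
#' the net metabolic rate outcome, and returns the raw-scale table ready for
#' anthropometric normalization and baseline z-scoring.
#'
#' @param trials list of `raw_trial` objects (must include each subject's
#'   baseline-condition trial, which also provides the EMG normalization).
#' @param registry feature registry (default: the 68-feature stage).
#' @param k_sd outlier threshold.
#' @return list: `table` (one row per trial; `norm_state` attribute
#'   `"raw"`), `outlier_report`, `excluded` variables, `baseline_strides`
#'   (per-subject stride-level baseline values for z-scoring statistics).
#' @export
build_feature_table <- function(trials,
                                registry = build_registry("post_moment_removal"),
                                k_sd = 3) {
  subj_of <- vapply(trials, function(tr) tr$subject$subject_id, character(1))
  is_base <- vapply(trials, function(tr) isTRUE(tr$config$baseline),
                    logical(1))
  emg_base <- list()
  for (s in unique(subj_of)) {
    bt <- which(subj_of == s & is_base)
    if (length(bt) == 0) stop("subject lacks a baseline trial: ", s)
    emg_base[[s]] <- emg_baseline_maxima(trials[[bt[1]]])
  }

  long <- list()
  outcomes <- list()
  for (k in seq_along(trials)) {
    tr <- trials[[k]]
    ex <- extract_trial(tr, emg_base[[tr$subject$subject_id]])
    df <- ex$strides
    df$subject_id <- tr$subject$subject_id
    df$trial_id <- tr$trial_id
    df$baseline <- isTRUE(tr$config$baseline)
    long[[k]] <- df
    outcomes[[k]] <- data.frame(
      trial_id = tr$trial_id, subject_id = tr$subject$subject_id,
      baseline = isTRUE(tr$config$baseline),
      subj_age = tr$subject$age, subj_mass = tr$subject$mass,
      subj_height = tr$subject$height,
      subj_sex = as.numeric(tr$subject$sex == "M"),
      subj_shoe_size = tr$subject$shoe_size,
      pros_power = tr$config$power, pros_stiffness = tr$config$stiffness,
      net_met_rate = ex$outcome, stringsAsFactors = FALSE)
  }
  long <- do.call(rbind, long)
  filtered <- remove_outliers(long, k_sd = k_sd)

  keep_vars <- setdiff(intersect(registry$name, unique(filtered$data$variable)),
                       filtered$excluded)
  agg <- stats::aggregate(value ~ trial_id + variable, data = filtered$data,
                          FUN = mean)
  wide <- stats::reshape(agg, idvar = "trial_id", timevar = "variable",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))

  meta <- do.call(rbind, outcomes)
  tab <- merge(meta, wide[, c("trial_id", keep_vars), drop = FALSE],
               by = "trial_id", sort = FALSE)
  ord <- c("trial_id", "subject_id", "baseline",
           intersect(registry$name, names(tab)), "net_met_rate")
  tab <- tab[, ord, drop = FALSE]
  attr(tab, "norm_state") <- "raw"
  attr(tab, "registry") <- registry

  base_strides <- filtered$data[filtered$data$baseline, , drop = FALSE]
  list(table = tab, outlier_report = filtered$report,
       excluded = filtered$excluded, baseline_strides = base_strides)
}

#' Stride-level baseline statistics for z-scoring
#'
#' Per subject and variable, the mean and SD over the retained baseline-trial
#' strides (all sessions pooled).
#'
#' @param baseline_strides long stride-level data frame from
#'   [build_feature_table()].
#' @return data frame `subject_id`, `variable`, `mean`, `sd`.
#' @export
baseline_stride_stats <- function(baseline_strides) {
  agg_m <- stats::aggregate(value ~ subject_id + variable,
                            data = baseline_strides, FUN = mean)
  agg_s <- stats::aggregate(value ~ subject_id + variable,
                            data = baseline_strides, FUN = sd)
  out <- merge(agg_m, agg_s, by = c("subject_id", "variable"),
               suffixes = c(".mean", ".sd"))
  names(out)[3:4] <- c("mean", "sd")
  out
}
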