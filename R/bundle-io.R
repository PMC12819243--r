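#' Write a raw trial to a plain-text bundle directory
#'
#' One directory per trial: `grf.tsv` (time_s, fx_l, fy_l, fz_l, fx_r, fy_r,
#' fz_r; N), `markers.tsv` (heel-marker xyz per side; m), `angles.tsv`
#' (joint-angle channels; deg), `emg.tsv` (one column per channel; mV),
#' `gases.tsv` and `resting.tsv` (breath-averaged vo2/vco2; mL/s) and
#' `meta.yaml` (subject, configuration, rates and the scalar ground truth;
#' the bulky truth series stay in the in-memory object only).
#'
#' @param trial a `raw_trial`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trial_bundle <- function(trial, dir) {
  stopifnot(inherits(trial, "raw_trial"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, f) {
    utils::write.table(df, file.path(dir, f), sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  wr(trial$grf, "grf.tsv")
  wr(trial$markers, "markers.tsv")
  wr(trial$angles, "angles.tsv")
  wr(trial$emg, "emg.tsv")
  wr(trial$gases, "gases.tsv")
  wr(trial$gases_resting, "resting.tsv")

  tv <- trial$true_values
  scalars <- tv[vapply(tv, function(x) is.numeric(x) && length(x) == 1,
                       logical(1))]
  meta <- list(
    trial_id = trial$trial_id,
    subject = as.list(trial$subject),
    config = as.list(trial$config[c("stiffness", "power", "stiffness_label",
                                    "power_label", "baseline")]),
    belt_speed_m_s = trial$belt_speed,
    fs_hz = trial$fs, fs_marker_hz = trial$fs_marker,
    duration_s = trial$duration,
    emg_channels = as.list(trial$emg_channels),
    true_values = scalars)
  yaml::write_yaml(meta, file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' Read a trial bundle directory back into a `raw_trial`
#'
#' @param dir bundle directory written by [write_trial_bundle()].
#' @return a `raw_trial` (ground truth restricted to the scalar values
#'   stored in `meta.yaml`).
#' @export
read_trial_bundle <- function(dir) {
  rd <- function(f) {
    utils::read.table(file.path(dir, f), sep = "\t", header = TRUE)
  }
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  structure(list(
    trial_id = meta$trial_id,
    subject = as.data.frame(meta$subject, stringsAsFactors = FALSE),
    config = as.data.frame(meta$config, stringsAsFactors = FALSE),
    belt_speed = meta$belt_speed_m_s,
    fs = meta$fs_hz, fs_marker = meta$fs_marker_hz,
    duration = meta$duration_s,
    grf = rd("grf.tsv"), markers = rd("markers.tsv"),
    angles = rd("angles.tsv"), emg = rd("emg.tsv"),
    emg_channels = unlist(meta$emg_channels),
    gases = rd("gases.tsv"), gases_resting = rd("resting.tsv"),
    true_values = meta$true_values), class = "raw_trial")
}
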