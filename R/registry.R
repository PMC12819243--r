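#' @title Feature registry
#' @description
#' The canonical enumeration of candidate model features for the
#' walking-with-powered-prosthesis analysis, in three stages:
#'
#' * `initial` / `post_moment_removal` (68 features): subject covariates (5),
#'   prosthesis settings (2), spatiotemporal parameters (6), individual-limb
#'   step-to-step transition work (8), integrated EMG (11: 4 affected-side,
#'   7 unaffected-side muscles), ground reaction force peaks (12) and
#'   stance-phase joint-angle peaks (24) — after joint moments and transverse
#'   ankle rotation are excluded. Affected-side ankle inversion/eversion is
#'   carried at this stage and leaves before the final set.
#' * `post_correlation_pruning` (62): one member of each strongly correlated
#'   anatomical pair (ankle inversion/eversion, hip internal/external
#'   rotation, hip abduction/adduction, both sides) removed.
#' * `final_table1` (50): the final model feature set.
#'
#' @name registry
NULL

muscles_affected <- c("biceps_femoris", "gluteus_maximus", "vastus_lateralis",
                      "rectus_femoris")
muscles_unaffected <- c(muscles_affected, "lateral_gastrocnemius", "soleus",
                        "tibialis_anterior")

registry_rows <- function() {
  row <- function(name, category, side, anthro_norm, zscored) {
    data.frame(name = name, category = category, side = side,
               anthro_norm = anthro_norm, zscored = zscored,
               stringsAsFactors = FALSE)
  }
  rows <- list(
    row("subj_age", "subject", "n/a", "none", FALSE),
    row("subj_mass", "subject", "n/a", "none", FALSE),
    row("subj_height", "subject", "n/a", "none", FALSE),
    row("subj_sex", "subject", "n/a", "none", FALSE),
    row("subj_shoe_size", "subject", "n/a", "none", FALSE),
    row("pros_power", "prosthesis", "n/a", "none", FALSE),
    row("pros_stiffness", "prosthesis", "n/a", "none", FALSE),
    row("spt_stride_length", "spatiotemporal", "n/a", "height", TRUE),
    row("spt_stance_time_affected", "spatiotemporal", "affected", "none", TRUE),
    row("spt_stance_time_unaffected", "spatiotemporal", "unaffected", "none", TRUE),
    row("spt_step_length_a2u", "spatiotemporal", "n/a", "height", TRUE),
    row("spt_step_length_u2a", "spatiotemporal", "n/a", "height", TRUE),
    row("spt_step_width", "spatiotemporal", "n/a", "height", TRUE))
  for (role in c("leading", "trailing")) {
    for (side in c("affected", "unaffected")) {
      for (sign in c("positive", "negative")) {
        rows[[length(rows) + 1]] <- row(
          paste("work", role, side, sign, sep = "_"),
          "transition_work", side, "mass", TRUE)
      }
    }
  }
  for (m in muscles_affected) {
    rows[[length(rows) + 1]] <- row(paste0("iemg_affected_", m),
                                    "muscle", "affected", "none", TRUE)
  }
  for (m in muscles_unaffected) {
    rows[[length(rows) + 1]] <- row(paste0("iemg_unaffected_", m),
                                    "muscle", "unaffected", "none", TRUE)
  }
  grf_vars <- c("vertical_peak1", "vertical_peak2", "braking", "propulsive",
                "medial", "lateral")
  for (side in c("affected", "unaffected")) {
    for (g in grf_vars) {
      rows[[length(rows) + 1]] <- row(paste("grf", side, g, sep = "_"),
                                      "grf", side, "mass", TRUE)
    }
  }
  angle_vars <- c("ankle_plantarflexion", "ankle_dorsiflexion",
                  "ankle_inversion", "ankle_eversion",
                  "knee_flexion", "knee_extension",
                  "hip_flexion", "hip_extension",
                  "hip_internal_rotation", "hip_external_rotation",
                  "hip_abduction", "hip_adduction")
  for (side in c("affected", "unaffected")) {
    for (a in angle_vars) {
      rows[[length(rows) + 1]] <- row(paste("angle", side, a, sep = "_"),
                                      "kinematics", side, "none", TRUE)
    }
  }
  do.call(rbind, rows)
}

# anatomical pairs pruned at |r| > 0.8: the second-listed member is removed
correlated_pair_victims <- function() {
  as.vector(outer(c("affected", "unaffected"),
                  c("ankle_eversion", "hip_external_rotation", "hip_adduction"),
                  function(s, a) paste("angle", s, a, sep = "_")))
}

# features of the 62-set that do not make the final 50-feature model
final_stage_dropped <- function() {
  c("subj_age",
    "spt_stride_length", "spt_step_length_a2u",
    "angle_affected_ankle_inversion", "angle_unaffected_hip_abduction",
    "iemg_affected_gluteus_maximus", "iemg_affected_vastus_lateralis",
    "iemg_unaffected_vastus_lateralis",
    "grf_affected_vertical_peak1", "grf_affected_braking",
    "grf_unaffected_lateral",
    "work_trailing_unaffected_negative")
}

#' Build the feature registry at a given selection stage
#'
#' @param stage one of `"initial"`, `"post_moment_removal"` (synonyms; 68
#'   features), `"post_correlation_pruning"` (62) or `"final_table1"` (50).
#' @return data frame with columns `name`, `category`, `side`, `anthro_norm`
#'   (`none`, `height` or `mass`: the anthropometric normalization divisor)
#'   and `zscored` (whether the feature is z-scored to the per-subject
#'   baseline condition), carrying the stage as attribute `"stage"`.
#' @examples
#' nrow(build_registry("post_moment_removal"))     # 68
#' nrow(build_registry("post_correlation_pruning")) # 62
#' nrow(build_registry("final_table1"))             # 50
#' @export
build_registry <- function(stage = c("initial", "post_moment_removal",
                                     "post_correlation_pruning",
                                     "final_table1")) {
  stage <- match.arg(stage)
  reg <- registry_rows()
  if (stage %in% c("post_correlation_pruning", "final_table1")) {
    reg <- reg[!reg$name %in% correlated_pair_victims(), , drop = FALSE]
  }
  if (stage == "final_table1") {
    reg <- reg[!reg$name %in% final_stage_dropped(), , drop = FALSE]
  }
  rownames(reg) <- NULL
  attr(reg, "stage") <- stage
  reg
}

#' Classify a Pearson correlation coefficient into interpretation bands
#'
#' Bands on the magnitude: below 0.4 weak, 0.4-0.69 moderate, 0.7-0.89
#' strong, 0.9-0.99 very strong, 1.0 perfect.
#'
#' @param r Pearson correlation coefficient(s) in \[-1, 1\].
#' @return character vector of band labels.
#' @export
classify_correlation <- function(r) {
  if (any(abs(r) > 1)) stop("|r| must not exceed 1")
  a <- abs(r)
  ifelse(a == 1, "perfect",
         ifelse(a >= 0.9, "very strong",
                ifelse(a >= 0.7, "strong",
                       ifelse(a >= 0.4, "moderate", "weak"))))
}
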