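#' Generate a synthetic study cohort
#'
#' Draws subject profiles matching the study population: unilateral
#' transtibial prosthesis users with age 41.5 +/- 8.5 years, body mass
#' (prosthesis included) 77.4 +/- 15.2 kg, height 1.75 +/- 0.08 m, a roughly
#' 3:10 female:male split, and prosthesis shoe sizes spanning 22-30 cm.
#' Normal draws are truncated to positive values (and shoe size to its
#' 22-30 cm range) by redrawing.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param seed integer RNG seed; the cohort is a pure function of
#'   `(n_subjects, seed)`.
#' @return data frame with one row per subject: `subject_id`, `age` (years),
#'   `mass` (kg), `height` (m), `sex` (`"F"`/`"M"`), `shoe_size` (cm),
#'   `affected_side` (`"left"`/`"right"`).
#' @export
generate_cohort <- function(n_subjects, seed = 1L) {
  if (length(n_subjects) != 1 || is.na(n_subjects) || n_subjects < 1) {
    stop("n_subjects must be a positive count")
  }
  n_subjects <- as.integer(n_subjects)
  set.seed(seed)

  rtrunc_norm <- function(n, mean, sd, lower = 0, upper = Inf) {
    x <- rnorm(n, mean, sd)
    bad <- which(x <= lower | x >= upper)
    while (length(bad) > 0) {
      x[bad] <- rnorm(length(bad), mean, sd)
      bad <- bad[x[bad] <= lower | x[bad] >= upper]
    }
    x
  }

  data.frame(
    subject_id = sprintf("S%02d", seq_len(n_subjects)),
    age = rtrunc_norm(n_subjects, 41.5, 8.5),
    mass = rtrunc_norm(n_subjects, 77.4, 15.2),
    height = rtrunc_norm(n_subjects, 1.75, 0.08),
    sex = ifelse(runif(n_subjects) < 3 / 13, "F", "M"),
    shoe_size = rtrunc_norm(n_subjects, 26, 2, lower = 22, upper = 30),
    affected_side = ifelse(runif(n_subjects) < 4 / 13, "left", "right"),
    stringsAsFactors = FALSE)
}

#' Enumerate the prosthesis configurations
#'
#' The 16 unique combinations of prosthetic foot stiffness category
#' (-2, -1, Rec, +1, coded -2..+1 with Rec = 0) and battery power setting
#' (NoPower, Rec, +10%, +20%, coded 0..3). The baseline condition is
#' (-1 stiffness, NoPower).
#'
#' @return data frame with `stiffness` (integer -2..1), `power` (integer
#'   0..3), `stiffness_label`, `power_label` and logical `baseline`.
#' @export
prosthesis_configs <- function() {
  cfg <- expand.grid(stiffness = -2:1, power = 0:3, KEEP.OUT.ATTRS = FALSE)
  cfg$stiffness_label <- c("-2", "-1", "Rec", "+1")[cfg$stiffness + 3]
  cfg$power_label <- c("NoPower", "Rec", "+10%", "+20%")[cfg$power + 1]
  cfg$baseline <- cfg$stiffness == -1 & cfg$power == 0
  cfg
}
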