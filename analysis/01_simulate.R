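#!/usr/bin/env Rscript
# Stage 1 — simulate the study data.
#
# Two synthetic layers: (a) the feature-level modeling cohort (13 subjects x
# 16 prosthesis configurations, 13 trials lost, five planted partial effects
# on net metabolic rate), written as cohort.csv + ground_truth.yaml; (b) one
# subject's raw-signal trial bundle (GRF / markers / angles / EMG / gases)
# for the mechanics stages.

library(gaitmet)

out <- "results"
dir.create(file.path(out, "bundles"), recursive = TRUE, showWarnings = FALSE)
seed <- 1L

sc <- standard_cohort(seed = seed)
write.csv(sc$table, file.path(out, "cohort.csv"), row.names = FALSE)
spec <- sc$truth$spec
yaml::write_yaml(list(
  intercept_w_kg = spec$intercept,
  noise_sd_w_kg = spec$noise_sd,
  effects = lapply(spec$effects, function(e) {
    e[c("feature", "shape", "amplitude", "direction", "center", "scale")]
  })), file.path(out, "ground_truth.yaml"))
cat(sprintf("modeling cohort: %d trials x %d features -> %s\n",
            nrow(sc$X), ncol(sc$X), file.path(out, "cohort.csv")))
cat(sprintf("planted effects: %s (amplitudes %s W/kg)\n",
            paste(sc$active, collapse = ", "),
            paste(sapply(spec$effects, `[[`, "amplitude"), collapse = "/")))

subj <- generate_cohort(1, seed = seed + 1L)
cfgs <- prosthesis_configs()
for (j in c(which(cfgs$baseline), which(cfgs$power == 3 & cfgs$stiffness == -1))) {
  tr <- generate_trial_signals(subj, cfgs[j, ], duration = 30,
                               seed = seed + 10L + j)
  dir <- file.path(out, "bundles", tr$trial_id)
  write_trial_bundle(tr, dir)
  cat(sprintf("trial bundle %s (%s stiffness, %s) -> %s\n", tr$trial_id,
              cfgs$stiffness_label[j], cfgs$power_label[j], dir))
}
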