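#' Pipeline run configuration
#'
#' Bundles every stage's parameters with one global seed. The defaults
#' reproduce the canonical analysis constants: 50 N event threshold, 7 Hz
#' fourth-order GRF/marker filtering, 20 Hz high-pass and 6 Hz low-pass
#' second-order EMG filtering, 3 SD outlier removal, |r| > 0.8 correlation
#' pruning, 20 VIP-test models, 1% selection tolerance, 5 CV folds and the
#' 40-trial / 50-replicate / 10-bin ALE bootstrap with the P90 - P10 effect
#' size.
#'
#' In `paper_replication` mode the pipeline consumes raw-signal trials and
#' uses the fixed anatomical pruning plus the final 50-feature registry; in
#' `discovery` mode it consumes the feature-level cohort and runs the full
#' data-driven VIP selection.
#'
#' @param mode `"paper_replication"` or `"discovery"`.
#' @param seed global integer seed, fanned out to stages by adding a stable
#'   per-stage offset derived from the stage name.
#' @param n_subjects,n_dropped,duration cohort parameters.
#' @param spec generator ground truth ([effect_spec()]).
#' @param grid hyperparameter grid for cross-validation (list of
#'   [bart_hyperparams()]); a length-1 grid skips CV.
#' @param cv_folds folds for [bart_cv()].
#' @param selection_hp hyperparameters for the VIP-test and feature-test
#'   fits.
#' @param n_vip_models VIP-test replicate count.
#' @param tolerance selection tolerance (proportion of the maximum
#'   pseudo-R-squared).
#' @param cor_threshold correlation-pruning threshold.
#' @param k_sd stride outlier threshold, SDs.
#' @param event_threshold gait-event force threshold, N.
#' @param ale list: `sample_size`, `n_reps`, `n_bins`, `thin`.
#' @param missing_rate missingness injected into the feature-level cohort
#'   (exercises the imputation stage; default 0).
#' @param out_dir output directory.
#' @return object of class `run_config`.
#' @export
run_config <- function(mode = c("discovery", "paper_replication"),
                       seed = 1L, n_subjects = 13L, n_dropped = 13L,
                       duration = 30,
                       spec = default_effect_spec(),
                       grid = list(bart_hyperparams()),
                       cv_folds = 5L,
                       selection_hp = bart_hyperparams(n_burn = 100L,
                                                       n_draws = 200L),
                       n_vip_models = 20L, tolerance = 0.01,
                       cor_threshold = 0.8, k_sd = 3,
                       event_threshold = 50,
                       ale = list(sample_size = 40L, n_reps = 50L,
                                  n_bins = 10L, thin = 5L),
                       missing_rate = 0,
                       out_dir = tempfile("gaitmet_run_")) {
  cfg <- structure(list(
    mode = match.arg(mode), seed = as.integer(seed),
    n_subjects = as.integer(n_subjects), n_dropped = as.integer(n_dropped),
    duration = duration, spec = spec, grid = grid,
    cv_folds = as.integer(cv_folds), selection_hp = selection_hp,
    n_vip_models = as.integer(n_vip_models), tolerance = tolerance,
    cor_threshold = cor_threshold, k_sd = k_sd,
    event_threshold = event_threshold, ale = ale,
    missing_rate = missing_rate, out_dir = out_dir),
    class = "run_config")
  validate_config(cfg)
  cfg
}

#' Validate a run configuration
#'
#' @param config a `run_config` (or plain list with the same fields).
#' @return `TRUE` invisibly, or an error listing every violation.
#' @export
validate_config <- function(config) {
  known <- c("mode", "seed", "n_subjects", "n_dropped", "duration", "spec",
             "grid", "cv_folds", "selection_hp", "n_vip_models", "tolerance",
             "cor_threshold", "k_sd", "event_threshold", "ale",
             "missing_rate", "out_dir")
  errs <- character(0)
  bad <- function(msg) errs <<- c(errs, msg)
  unknown <- setdiff(names(config), known)
  if (length(unknown)) bad(paste("unknown keys:", paste(unknown, collapse = ", ")))
  if (!config$mode %in% c("discovery", "paper_replication")) bad("mode: invalid")
  if (config$n_subjects < 1) bad("n_subjects: must be >= 1")
  if (config$tolerance < 0 || config$tolerance >= 1) bad("tolerance: out of [0, 1)")
  if (config$cor_threshold <= 0 || config$cor_threshold > 1) bad("cor_threshold: out of (0, 1]")
  if (config$k_sd <= 0) bad("k_sd: must be positive")
  if (config$event_threshold <= 0) bad("event_threshold: must be positive")
  if (config$cv_folds < 2) bad("cv_folds: must be >= 2")
  if (config$n_vip_models < 1) bad("n_vip_models: must be >= 1")
  if (length(config$grid) < 1) bad("grid: must be nonempty")
  if (config$missing_rate < 0 || config$missing_rate >= 1) bad("missing_rate: out of [0, 1)")
  with(config$ale, {
    if (sample_size < 2) bad("ale$sample_size: must be >= 2")
    if (n_reps < 1) bad("ale$n_reps: must be >= 1")
    if (n_bins < 1) bad("ale$n_bins: must be >= 1")
  })
  if (!inherits(config$spec, "effect_spec")) bad("spec: not an effect_spec")
  if (length(errs)) stop("invalid configuration:\n  ",
                         paste(errs, collapse = "\n  "))
  invisible(TRUE)
}

# stable per-stage seed offsets below 2^31
stage_seed <- function(seed, stage) {
  seed + sum(utf8ToInt(stage)) %% 9973L
}

write_stage_csv <- function(df, config, file) {
  path <- file.path(config$out_dir, file)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' simulate, extract (signal mode), build table, fit, select, compute ALE
#' effects and write the report files plus a run manifest
#' (`run_manifest.json`: configuration echo, seed, per-file MD5 checksums)
#' into the configured output directory. Reruns with the same configuration
#' are byte-identical for the deterministic artifacts.
#'
#' @param config a [run_config()].
#' @return list of stage results (invisibly returns file paths in
#'   `$files`).
#' @export
run_all <- function(config = run_config()) {
  validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- if (config$mode == "paper_replication") {
    run_signal_pipeline(config)
  } else {
    run_feature_pipeline(config)
  }

  files <- list.files(config$out_dir, full.names = TRUE,
                      pattern = "\\.(csv|json)$")
  files <- setdiff(files, file.path(config$out_dir, "run_manifest.json"))
  manifest <- list(
    mode = config$mode, seed = config$seed,
    package_version = as.character(utils::packageVersion("gaitmet")),
    n_subjects = config$n_subjects,
    checksums = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(config$out_dir,
                                           "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$files <- c(files, file.path(config$out_dir, "run_manifest.json"))
  invisible(res)
}

run_feature_pipeline <- function(config) {
  subjects <- generate_cohort(config$n_subjects,
                              seed = stage_seed(config$seed, "cohort"))
  gen <- generate_feature_table(subjects, spec = config$spec,
                                seed = stage_seed(config$seed, "features"),
                                n_dropped = config$n_dropped)
  registry <- attr(gen$table, "registry")
  tab <- gen$table
  if (config$missing_rate > 0) {
    tab <- inject_missingness(tab, config$missing_rate,
                              seed = stage_seed(config$seed, "missing"))
    tab <- impute_missing(tab, seed = stage_seed(config$seed, "impute"))
  }
  model_tab <- tab[!tab$baseline, , drop = FALSE]
  X <- as.data.frame(model_tab[, registry$name, drop = FALSE])
  y <- model_tab$net_met_rate
  write_stage_csv(model_tab, config, "features_z.csv")

  pr <- prune_correlated(X, threshold = config$cor_threshold, pairs = NULL)
  write_stage_csv(pr$removed, config, "pruning_log.csv")
  X <- pr$X

  vip <- average_vip(X, y, n_models = config$n_vip_models,
                     hp = config$selection_hp,
                     seed = stage_seed(config$seed, "vip"))
  write_stage_csv(data.frame(feature = names(vip), mean_vip = vip,
                             rank = seq_along(vip)),
                  config, "ranking.csv")
  curve <- incremental_curve(names(vip), X, y, hp = config$selection_hp,
                             seed = stage_seed(config$seed, "curve"))
  write_stage_csv(as.data.frame(curve), config, "selection_curve.csv")
  k <- select_k(curve, tolerance = config$tolerance)
  selected <- names(vip)[seq_len(k)]

  fit_stage(config, X[, selected, drop = FALSE], y, model_tab$subject_id,
            selected, truth = gen$truth)
}

run_signal_pipeline <- function(config) {
  subjects <- generate_cohort(config$n_subjects,
                              seed = stage_seed(config$seed, "cohort"))
  configs <- prosthesis_configs()
  trials <- list()
  tseed <- stage_seed(config$seed, "signals")
  for (i in seq_len(nrow(subjects))) {
    for (j in seq_len(nrow(configs))) {
      trials[[length(trials) + 1]] <- generate_trial_signals(
        subjects[i, ], configs[j, ], duration = config$duration,
        seed = tseed + 101L * i + j)
    }
  }

  built <- build_feature_table(trials)
  write_stage_csv(built$outlier_report, config, "outlier_report.csv")
  registry <- attr(built$table, "registry")
  tab <- normalize_anthro(built$table, subjects, registry)
  write_stage_csv(tab, config, "features_raw.csv")

  base_strides <- normalize_baseline_strides(built$baseline_strides,
                                             subjects, registry)
  zs <- zscore_to_baseline(tab, registry,
                           baseline_stats = baseline_stride_stats(base_strides))
  write_stage_csv(zs$baseline_stats, config, "baseline_stats.csv")
  model_tab <- impute_missing(zs$table,
                              seed = stage_seed(config$seed, "impute"))
  write_stage_csv(model_tab, config, "features_z.csv")

  # replication-mode selection: fixed anatomical pruning, fixed final set
  final <- build_registry("final_table1")
  X <- as.data.frame(model_tab[, intersect(final$name, names(model_tab)),
                               drop = FALSE])
  y <- model_tab$net_met_rate
  fit_stage(config, X, y, model_tab$subject_id, names(X), truth = NULL)
}

# divide stride-level baseline values by the registry anthropometric rule
normalize_baseline_strides <- function(baseline_strides, subjects, registry) {
  i <- match(baseline_strides$subject_id, subjects$subject_id)
  rule <- registry$anthro_norm[match(baseline_strides$variable,
                                     registry$name)]
  div <- ifelse(is.na(rule) | rule == "none", 1,
                ifelse(rule == "height", subjects$height[i],
                       subjects$mass[i]))
  baseline_strides$value <- baseline_strides$value / div
  baseline_strides
}

fit_stage <- function(config, X, y, subject, selected, truth) {
  if (length(config$grid) > 1) {
    cv <- bart_cv(X, y, grid = config$grid, k = config$cv_folds,
                  subject = subject,
                  seed = stage_seed(config$seed, "cv"))
    hp <- cv$best
    cv_table <- cv$cv_table
  } else {
    hp <- config$grid[[1]]
    cv_table <- NULL
  }
  hp$seed <- stage_seed(config$seed, "fit")
  model <- bart_fit(X, y, hp)

  summary_json <- list(
    hyperparameters = hp[c("n_trees", "k", "nu", "q", "alpha", "beta",
                           "n_burn", "n_draws")],
    pseudo_r2 = pseudo_r2(model),
    normalized_rmse_pct = normalized_rmse(model),
    rmse = model_rmse(model),
    seed = config$seed, n_rows = nrow(X), n_features = ncol(X))
  jsonlite::write_json(summary_json,
                       file.path(config$out_dir, "model_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_stage_csv(data.frame(feature = names(bart_vip(model)),
                             vip = bart_vip(model)),
                  config, "vip.csv")
  if (!is.null(cv_table)) write_stage_csv(cv_table, config, "cv_table.csv")

  aseed <- stage_seed(config$seed, "ale")
  boots <- list()
  curves <- list()
  for (i in seq_along(selected)) {
    f <- selected[i]
    b <- bootstrap_ale(model, X, f,
                       sample_size = min(config$ale$sample_size, nrow(X)),
                       n_reps = config$ale$n_reps,
                       n_bins = config$ale$n_bins,
                       seed = aseed + i, thin = config$ale$thin)
    boots[[f]] <- b
    cb <- b$bins
    cb$feature <- f
    cb$units <- "W/kg"
    curves[[f]] <- cb
  }
  write_stage_csv(do.call(rbind, curves), config, "ale_curves.csv")
  report <- effect_report(boots, model_rmse(model))
  report$units <- "W/kg"
  write_stage_csv(report, config, "effect_sizes.csv")

  list(model = model, report = report, bootstraps = boots,
       selected = selected, cv_table = cv_table, truth = truth,
       X = X, y = y)
}
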