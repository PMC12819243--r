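#' Extract stance-phase peaks from a time series
#'
#' In `bidirectional` mode the signed extrema (maximum and minimum) within
#' each window are returned — the per-direction peaks of joint angles and
#' shear GRFs. In `vertical_grf` mode the two largest local maxima separated
#' by a local minimum are returned in time order (weight-acceptance and
#' push-off peaks); windows without a two-peak structure are flagged and the
#' second peak left missing (imputable downstream).
#'
#' @param x signal values.
#' @param time sample times, s.
#' @param windows data frame with `start`, `end` times (stance windows).
#' @param mode `"bidirectional"` or `"vertical_grf"`.
#' @return data frame per window: `peak_max`/`peak_min`, or
#'   `peak1`/`peak2`/`single_peak`.
#' @export
extract_peaks <- function(x, time, windows,
                          mode = c("bidirectional", "vertical_grf")) {
  mode <- match.arg(mode)
  out <- lapply(seq_len(nrow(windows)), function(w) {
    idx <- which(time >= windows$start[w] & time < windows$end[w])
    if (length(idx) < 3) stop("stance window outside series support")
    v <- x[idx]
    if (mode == "bidirectional") {
      return(data.frame(window = w, peak_max = max(v), peak_min = min(v)))
    }
    d <- diff(v)
    lmax <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1
    if (length(lmax) >= 2) {
      top2 <- lmax[order(v[lmax], decreasing = TRUE)[1:2]]
      top2 <- sort(top2)
      # a genuine local minimum must separate the two maxima
      sep <- min(v[top2[1]:top2[2]]) < min(v[top2])
      if (sep) {
        return(data.frame(window = w, peak1 = v[top2[1]], peak2 = v[top2[2]],
                          single_peak = FALSE))
      }
    }
    data.frame(window = w, peak1 = max(v), peak2 = NA_real_,
               single_peak = TRUE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Remove per-stride outliers beyond k standard deviations
#'
#' Single-pass removal within each group (subject by variable): each value is
#' compared against the mean and SD of the other values in its group
#' (leave-one-out, so a gross outlier cannot mask itself by inflating the
#' group SD) and dropped when it lies more than `k_sd` SDs away. Groups
#' smaller than 3 are skipped with a warning. Variables whose removal
#' fraction exceeds `max_fraction` are reported for exclusion from the
#' registry (mirroring the exclusion of transverse ankle rotation).
#'
#' @param data long data frame of stride-level values.
#' @param value_col name of the value column.
#' @param group_cols grouping columns (default subject and variable).
#' @param k_sd outlier threshold in SDs (default 3).
#' @param max_fraction per-variable removal fraction above which the
#'   variable is excluded (default 0.30).
#' @return list: `data` (filtered), `report` (per-variable removal
#'   fraction), `excluded` (variables over the threshold).
#' @export
remove_outliers <- function(data, value_col = "value",
                            group_cols = c("subject_id", "variable"),
                            k_sd = 3, max_fraction = 0.30) {
  key <- interaction(data[group_cols], drop = TRUE)
  keep <- rep(TRUE, nrow(data))
  for (g in levels(key)) {
    idx <- which(key == g)
    n <- length(idx)
    if (n < 3) {
      warning("group too small, skipped: ", g)
      next
    }
    v <- data[[value_col]][idx]
    s_tot <- sum(v)
    ss_tot <- sum(v^2)
    m_loo <- (s_tot - v) / (n - 1)
    var_loo <- pmax(ss_tot - v^2 - (n - 1) * m_loo^2, 0) / (n - 2)
    s_loo <- sqrt(var_loo)
    dev <- abs(v - m_loo)
    keep[idx] <- ifelse(s_loo > 0, dev <= k_sd * s_loo, dev == 0)
  }
  removed <- !keep
  report <- stats::aggregate(removed,
                             by = list(variable = data$variable),
                             FUN = mean)
  names(report)[2] <- "removal_fraction"
  excluded <- report$variable[report$removal_fraction > max_fraction]
  list(data = data[keep, , drop = FALSE], report = report,
       excluded = as.character(excluded))
}

#' Anthropometric normalization of a feature table
#'
#' Divides each feature by the registry-designated divisor: subject height
#' (m) for stride length, step lengths and step width; body mass including
#' the prosthesis (kg) for transition work and GRFs. A table can only be
#' normalized once (state flag guard).
#'
#' @param table trial-by-feature data frame with a `subject_id` column.
#' @param subjects cohort data frame supplying `mass` and `height`.
#' @param registry feature registry (supplies the `anthro_norm` rule).
#' @return the normalized table, with `norm_state` attribute `"anthro"`.
#' @export
normalize_anthro <- function(table, subjects, registry) {
  state <- attr(table, "norm_state")
  if (!is.null(state) && state != "raw") {
    stop("table is already normalized (state: ", state, ")")
  }
  i <- match(table$subject_id, subjects$subject_id)
  if (anyNA(i)) stop("missing anthropometry for some subjects")
  divisor <- list(height = subjects$height[i], mass = subjects$mass[i])
  for (k in which(registry$anthro_norm != "none")) {
    nm <- registry$name[k]
    if (nm %in% names(table)) {
      table[[nm]] <- table[[nm]] / divisor[[registry$anthro_norm[k]]]
    }
  }
  attr(table, "norm_state") <- "anthro"
  table
}

#' Z-score features to each subject's baseline condition
#'
#' The baseline is the (-1 stiffness, no power) configuration. For each
#' subject and z-scored feature (and the net metabolic rate outcome),
#' `z = (x - mu_base) / sigma_base`. The baseline mean and SD come from the
#' per-stride values of the subject's baseline trial(s) when stride-level
#' statistics are supplied; otherwise the mean is taken over the subject's
#' baseline rows, and when that leaves the SD undefined (a single baseline
#' trial) or zero, the pooled across-subject SD of the feature is used as a
#' fallback and flagged. Baseline rows are excluded from the returned
#' modeling table.
#'
#' @param table trial-level table with `subject_id`, logical `baseline`,
#'   feature columns and `net_met_rate`.
#' @param registry feature registry (designates which features are z-scored).
#' @param baseline_stats optional data frame `subject_id`, `variable`,
#'   `mean`, `sd` from baseline-trial strides.
#' @return list: `table` (z-scored, baseline rows removed, `norm_state`
#'   attribute `"z"`), `baseline_stats` (the statistics used, with a
#'   `pooled_sd` flag).
#' @export
zscore_to_baseline <- function(table, registry, baseline_stats = NULL) {
  if (!all(c("subject_id", "baseline") %in% names(table))) {
    stop("table must carry subject_id and baseline columns")
  }
  subjects <- unique(table$subject_id)
  no_base <- subjects[!subjects %in% table$subject_id[table$baseline]]
  if (length(no_base) > 0) {
    stop("subjects lacking a baseline trial: ", paste(no_base, collapse = ", "))
  }
  zvars <- c(intersect(registry$name[registry$zscored], names(table)),
             "net_met_rate")
  stats_out <- list()
  ztab <- table
  for (s in subjects) {
    rows <- table$subject_id == s
    base <- rows & table$baseline
    for (v in zvars) {
      given <- if (!is.null(baseline_stats)) {
        baseline_stats[baseline_stats$subject_id == s &
                         baseline_stats$variable == v, , drop = FALSE]
      }
      if (!is.null(given) && nrow(given) == 1 && is.finite(given$sd) &&
          given$sd > 0) {
        mu <- given$mean
        sg <- given$sd
        pooled <- FALSE
      } else {
        mu <- mean(table[[v]][base])
        sg <- if (sum(base) >= 2) sd(table[[v]][base]) else NA_real_
        pooled <- !is.finite(sg) || sg == 0
        if (pooled) sg <- sd(table[[v]])  # pooled across-subject fallback
        if (!is.finite(sg) || sg == 0) sg <- 1  # constant feature: z = 0
      }
      ztab[[v]][rows] <- (table[[v]][rows] - mu) / sg
      stats_out[[length(stats_out) + 1]] <- data.frame(
        subject_id = s, variable = v, mean = mu, sd = sg, pooled_sd = pooled,
        stringsAsFactors = FALSE)
    }
  }
  out <- ztab[!ztab$baseline, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "norm_state") <- "z"
  attr(out, "registry") <- registry
  list(table = out, baseline_stats = do.call(rbind, stats_out))
}

#' Invert baseline z-scoring using stored statistics
#'
#' @param ztable z-scored table from [zscore_to_baseline()].
#' @param baseline_stats the statistics returned alongside it.
#' @return table on the original scale.
#' @export
unzscore <- function(ztable, baseline_stats) {
  for (k in seq_len(nrow(baseline_stats))) {
    s <- baseline_stats$subject_id[k]
    v <- baseline_stats$variable[k]
    rows <- ztable$subject_id == s
    ztable[[v]][rows] <- ztable[[v]][rows] * baseline_stats$sd[k] +
      baseline_stats$mean[k]
  }
  attr(ztable, "norm_state") <- "anthro"
  ztable
}

#' Random-forest imputation of missing feature cells
#'
#' missForest-style iterative scheme: missing cells start at their column
#' means, then each incomplete column is repeatedly re-fit with a regression
#' forest on all other features and its missing entries refreshed, until the
#' normalized change in imputed values stops decreasing. Observed cells are
#' never altered.
#'
#' @param table feature table (numeric feature columns may contain `NA`).
#' @param seed RNG seed (forests are fitted single-threaded for a
#'   deterministic completion).
#' @param max_iter iteration cap.
#' @param num_trees forest size per column.
#' @return the completed table.
#' @export
impute_missing <- function(table, seed = 1L, max_iter = 10L,
                           num_trees = 100L) {
  num_cols <- names(table)[vapply(table, is.numeric, logical(1))]
  miss <- vapply(table[num_cols], function(x) mean(is.na(x)), numeric(1))
  if (any(miss == 1)) {
    stop("all-missing column: ", paste(num_cols[miss == 1], collapse = ", "))
  }
  if (any(miss > 0.5)) {
    stop("per-feature missingness above 50%: ",
         paste(num_cols[miss > 0.5], collapse = ", "))
  }
  incomplete <- num_cols[miss > 0]
  if (length(incomplete) == 0) return(table)
  incomplete <- incomplete[order(miss[incomplete])]

  filled <- table
  for (v in incomplete) {
    filled[[v]][is.na(filled[[v]])] <- mean(filled[[v]], na.rm = TRUE)
  }
  predictors <- num_cols
  prev_delta <- Inf
  prev_filled <- filled
  for (it in seq_len(max_iter)) {
    set.seed(seed + it)
    old <- filled
    for (v in incomplete) {
      obs <- !is.na(table[[v]])
      dat <- filled[predictors]
      fit <- ranger::ranger(
        x = dat[obs, setdiff(predictors, v), drop = FALSE],
        y = table[[v]][obs],
        num.trees = num_trees, seed = seed + it, num.threads = 1)
      pred <- predict(fit, dat[!obs, setdiff(predictors, v), drop = FALSE],
                      num.threads = 1)$predictions
      filled[[v]][!obs] <- pred
    }
    delta <- sum(vapply(incomplete, function(v) {
      sum((filled[[v]] - old[[v]])^2)
    }, numeric(1))) / sum(vapply(incomplete, function(v) {
      sum(filled[[v]]^2)
    }, numeric(1)))
    if (delta >= prev_delta) {
      filled <- prev_filled  # change norm stopped decreasing: keep previous
      break
    }
    prev_delta <- delta
    prev_filled <- filled
  }
  filled
}
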