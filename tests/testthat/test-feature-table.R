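test_that("peak extraction finds signed extrema and double peaks", {
  t <- seq(0, 1, by = 0.001)
  win <- data.frame(start = 0.1, end = 0.9)
  # monotone ramp peaks at the window's trailing edge
  pk <- extract_peaks(t, t, win)
  expect_equal(pk$peak_max, 0.899, tolerance = 1e-6)
  # sinusoid peaks at +/- amplitude
  s <- 2.5 * sin(2 * pi * 2 * t)
  pk <- extract_peaks(s, t, win)
  expect_equal(pk$peak_max, 2.5, tolerance = 1e-3)
  expect_equal(pk$peak_min, -2.5, tolerance = 1e-3)

  # two-bump curve: both vertical-GRF peaks, in time order
  bump <- 800 * exp(-((t - 0.3)^2) / 0.002) + 700 * exp(-((t - 0.7)^2) / 0.002)
  pk <- extract_peaks(bump, t, data.frame(start = 0, end = 1),
                      mode = "vertical_grf")
  expect_false(pk$single_peak)
  expect_equal(pk$peak1, 800, tolerance = 1)
  expect_equal(pk$peak2, 700, tolerance = 1)
  # single bump flags and leaves the second peak missing
  pk1 <- extract_peaks(800 * exp(-((t - 0.5)^2) / 0.002), t,
                       data.frame(start = 0, end = 1), mode = "vertical_grf")
  expect_true(pk1$single_peak)
  expect_true(is.na(pk1$peak2))
})

test_that("synthetic vertical GRF peaks match generator truth", {
  tr <- fixture_trial()
  ex <- extract_trial(tr)
  agg <- aggregate(value ~ variable, ex$strides, mean)
  get <- function(v) agg$value[agg$variable == v]
  for (side in c("affected", "unaffected")) {
    for (pk in c("vertical_peak1", "vertical_peak2")) {
      nm <- paste0("grf_", side, "_", pk)
      expect_lt(abs(get(nm) - tr$true_values[[nm]]) / tr$true_values[[nm]],
                0.02)
    }
  }
})

test_that("outlier removal drops gross outliers and flags bad variables", {
  d <- data.frame(subject_id = "S01", variable = "v",
                  value = c(1, 1, 1, 1, 100))
  out <- remove_outliers(d)
  # brute-force leave-one-out oracle
  keep_oracle <- vapply(seq_len(5), function(i) {
    m <- mean(d$value[-i]); s <- sd(d$value[-i])
    if (s > 0) abs(d$value[i] - m) <= 3 * s else d$value[i] == m
  }, logical(1))
  expect_equal(out$data$value, d$value[keep_oracle])
  expect_false(100 %in% out$data$value)

  # all-equal values: zero SD, nothing removed
  d2 <- data.frame(subject_id = "S01", variable = "v", value = rep(5, 10))
  expect_equal(nrow(remove_outliers(d2)$data), 10)

  # a variable losing more than 30% of values is marked excluded
  set.seed(1)
  d3 <- rbind(
    data.frame(subject_id = "S01", variable = "good",
               value = rnorm(100)),
    data.frame(subject_id = "S01", variable = "bad",
               value = c(rnorm(60), rnorm(40, 0, 60))))
  # force removals by constructing a variable whose removal fraction
  # exceeds 0.30 under an artificially tight threshold
  out3 <- remove_outliers(d3, k_sd = 0.3, max_fraction = 0.30)
  expect_true("bad" %in% out3$excluded || "good" %in% out3$excluded)
  expect_true(all(out3$report$removal_fraction >= 0))

  # single-pass removal is order independent
  d4 <- data.frame(subject_id = "S01", variable = "v",
                   value = c(4, 2, 50, 1, 3))
  a <- remove_outliers(d4)$data$value
  b <- remove_outliers(d4[order(d4$value), ])$data$value
  expect_equal(sort(a), sort(b))

  expect_warning(remove_outliers(
    data.frame(subject_id = "S01", variable = "v", value = c(1, 2))),
    "too small")
})

test_that("anthropometric normalization divides by the registry rule once", {
  reg <- build_registry("post_moment_removal")
  subjects <- data.frame(subject_id = "S01", mass = 80, height = 1.75)
  tab <- data.frame(subject_id = "S01", spt_step_width = 0.175,
                    work_leading_affected_positive = 40,
                    spt_stance_time_affected = 0.7)
  attr(tab, "norm_state") <- "raw"
  out <- normalize_anthro(tab, subjects, reg)
  expect_equal(out$spt_step_width, 0.10)
  expect_equal(out$work_leading_affected_positive, 0.5)
  expect_equal(out$spt_stance_time_affected, 0.7)  # z-only, untouched
  expect_error(normalize_anthro(out, subjects, reg), "already normalized")
  expect_error(normalize_anthro(tab, subjects[0, ], reg), "anthropometry")
})

test_that("baseline z-scoring keeps 182 of 195 trials and centers baselines", {
  subjects <- generate_cohort(13, seed = 1)
  gen <- generate_feature_table(subjects, seed = 2, n_dropped = 13)
  reg <- attr(gen$table, "registry")
  zs <- zscore_to_baseline(gen$table, reg)
  expect_equal(nrow(gen$table), 195)
  expect_equal(nrow(zs$table), 182)
  expect_false(any(zs$table$baseline))

  # a feature equal to its baseline mean lands at z = 0: check via stats
  st <- zs$baseline_stats
  one <- st[st$subject_id == "S01" & st$variable == "spt_step_width", ]
  raw <- gen$table[gen$table$subject_id == "S01" & !gen$table$baseline, ]
  expect_equal(zs$table$spt_step_width[zs$table$subject_id == "S01"],
               (raw$spt_step_width - one$mean) / one$sd)

  # +2 SD shift of the modeling rows reads as z + 2 under fixed stats
  shifted <- gen$table
  nb <- !shifted$baseline
  shifted$spt_step_width[nb] <- shifted$spt_step_width[nb] + 2 * one$sd
  st_fixed <- st[st$variable == "spt_step_width", ]
  zs2 <- zscore_to_baseline(shifted, reg, baseline_stats = st_fixed)
  s01 <- zs$table$subject_id == "S01"
  expect_equal(zs2$table$spt_step_width[s01] -
                 zs$table$spt_step_width[s01],
               rep(2, sum(s01)), tolerance = 1e-9)

  # round trip recovers raw values exactly
  back <- unzscore(zs$table, zs$baseline_stats)
  raw_all <- gen$table[!gen$table$baseline, ]
  expect_equal(back$spt_step_width, raw_all$spt_step_width,
               tolerance = 1e-12)

  no_base <- gen$table[!gen$table$baseline, ]
  expect_error(zscore_to_baseline(no_base, reg), "lacking a baseline")
})

test_that("forest imputation restores redundant structure deterministically", {
  subjects <- generate_cohort(8, seed = 4)
  gen <- generate_feature_table(subjects, seed = 4)
  tab <- gen$table

  expect_identical(impute_missing(tab, seed = 1), tab)  # nothing missing

  # duplicate one column, mask 5%, and demand near-perfect recovery
  tab$dup <- tab$spt_step_width
  set.seed(9)
  mask <- sample(nrow(tab), round(0.05 * nrow(tab)))
  truth <- tab$dup[mask]
  tab$dup[mask] <- NA
  done <- impute_missing(tab, seed = 2)
  expect_false(anyNA(done$dup))
  expect_gt(cor(done$dup[mask], truth), 0.95)
  # observed cells are untouched
  expect_identical(done$dup[-mask], tab$dup[-mask])
  expect_identical(impute_missing(tab, seed = 2)$dup, done$dup)

  tab$gone <- NA_real_
  expect_error(impute_missing(tab, seed = 1), "all-missing")
})
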