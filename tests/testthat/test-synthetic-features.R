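test_that("noiseless single linear effect reproduces the outcome exactly", {
  subjects <- generate_cohort(3, seed = 1)
  spec <- effect_spec(list(
    list(feature = "spt_step_width", shape = "linear", amplitude = 0.5)),
    noise_sd = 0, intercept = 2)
  gen <- generate_feature_table(subjects, spec = spec, seed = 4)
  tab <- gen$table
  expect_equal(tab$net_met_rate - 2,
               true_partial_effect(spec, "spt_step_width",
                                   tab$spt_step_width))
})

test_that("13 subjects x 16 configs with 13 dropped emits 195 trials", {
  subjects <- generate_cohort(13, seed = 1)
  gen <- generate_feature_table(subjects, seed = 2, n_dropped = 13)
  expect_equal(nrow(gen$table), 195)
  # dropped trials are never the baseline condition
  expect_equal(sum(gen$table$baseline), 13)
  expect_equal(ncol(gen$table) - 4, 50)  # keys + 50 features + outcome
})

test_that("feature generation is deterministic under seed", {
  subjects <- generate_cohort(4, seed = 3)
  a <- generate_feature_table(subjects, seed = 9, n_dropped = 5)
  b <- generate_feature_table(subjects, seed = 9, n_dropped = 5)
  expect_identical(a$table, b$table)
  expect_identical(a$truth$partials, b$truth$partials)
})

test_that("unknown effect features raise a registry mismatch", {
  subjects <- generate_cohort(2, seed = 1)
  bad <- effect_spec(list(
    list(feature = "not_a_feature", shape = "linear", amplitude = 0.3)))
  expect_error(generate_feature_table(subjects, spec = bad, seed = 1),
               "missing from registry")
})

test_that("outcome variance decomposes into partial effects plus noise", {
  # many rows so the empirical variance stabilizes; independent features so
  # the partial-effect variances add without covariance terms
  subjects <- generate_cohort(125, seed = 6)
  gen <- generate_feature_table(subjects, seed = 7, rho = 0)
  expect_gte(nrow(gen$table), 2000)
  v_emp <- var(gen$table$net_met_rate)
  v_model <- sum(apply(gen$truth$partials, 2, var)) +
    gen$truth$spec$noise_sd^2
  expect_lt(abs(v_emp - v_model) / v_model, 0.10)

  # under the default block correlation the full identity (including
  # effect covariances) still holds
  gen2 <- generate_feature_table(subjects, seed = 7)
  v_emp2 <- var(gen2$table$net_met_rate)
  v_model2 <- var(rowSums(gen2$truth$partials)) + gen2$truth$spec$noise_sd^2
  expect_lt(abs(v_emp2 - v_model2) / v_model2, 0.10)
})

test_that("within-category block correlation is near its target", {
  subjects <- generate_cohort(60, seed = 8)
  gen <- generate_feature_table(subjects, seed = 8)
  tab <- gen$table
  r_within <- cor(tab$work_leading_affected_positive,
                  tab$work_trailing_affected_positive)
  expect_equal(r_within, 0.5, tolerance = 0.08)
})

test_that("missingness injection masks at the nominal rate and is safe", {
  subjects <- generate_cohort(13, seed = 1)
  gen <- generate_feature_table(subjects, seed = 2, n_dropped = 13)
  tab <- gen$table

  expect_identical(inject_missingness(tab, 0), tab)

  m <- inject_missingness(tab, 0.01, seed = 5)
  n_missing <- sum(is.na(m))
  reg <- attr(tab, "registry")
  maskable <- setdiff(reg$name, c("pros_power", "pros_stiffness"))
  expected <- nrow(tab) * length(maskable) * 0.01
  # binomial count within 4 SDs of its expectation
  expect_lt(abs(n_missing - expected), 4 * sqrt(expected) + 1)
  expect_false(anyNA(m$net_met_rate))
  expect_false(anyNA(m$subject_id))
  expect_false(anyNA(m$pros_power))

  expect_identical(inject_missingness(tab, 0.01, seed = 5), m)
  expect_error(inject_missingness(tab, 1), "rate")
})
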