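test_that("EMG chain rejects DC and recovers burst plateaus", {
  fs <- 1000
  t <- seq(0, 6, by = 1 / fs)
  expect_equal(process_emg(rep(0, length(t)), fs), rep(0, length(t)))
  # constant offset dies in the demean + high-pass stages
  env_dc <- process_emg(rep(2.5, length(t)), fs)
  expect_lt(max(env_dc), 1e-8)

  # sustained 80 Hz sinusoid of amplitude a: envelope plateau ~ 2a/pi
  a <- 1.4
  env <- process_emg(a * sin(2 * pi * 80 * t), fs)
  plateau <- median(env[t > 1 & t < 5])
  expect_lt(abs(plateau - 2 * a / pi) / (2 * a / pi), 0.05)
  expect_error(process_emg(rep(0, 50), fs = 50), "sampling")
})

test_that("EMG chain is linear in the input before clamping", {
  set.seed(1)
  fs <- 1000
  tt <- seq(0, 2, by = 1 / fs)
  x <- rnorm(2001) * exp(-((tt - 1)^2) / (2 * 0.2^2))
  e1 <- process_emg(x, fs)
  e3 <- process_emg(3 * x, fs)
  expect_equal(e3, 3 * e1, tolerance = 1e-8)
})

test_that("normalization divides by the mean baseline maximum", {
  env <- c(0.2, 1.0, 0.4)
  out <- normalize_emg(env, c(1, 2, 3))
  expect_equal(as.numeric(out), env / 2)
  expect_equal(attr(out, "baseline_max"), 2)
  # doubling the signal doubles normalized maxima
  out2 <- normalize_emg(2 * env, c(1, 2, 3))
  expect_equal(max(out2), 2 * max(out))
  expect_warning(bad <- normalize_emg(env, c(0, 0, 0)), "invalid")
  expect_true(all(is.na(bad)))
  expect_false(attr(bad, "valid"))
  expect_error(normalize_emg(env, c(1, 2)), "baseline strides")
})

test_that("iEMG is the windowed integral of the envelope", {
  t <- seq(0, 2, by = 0.001)
  expect_equal(iemg(rep(1, length(t)), t, 0.5, 1.5), 1.0, tolerance = 1e-9)
  expect_equal(iemg(rep(0, length(t)), t, 0.5, 1.5), 0)
  # triangle of peak 1 spanning 1 s has area 0.5
  tri <- pmax(1 - abs(t - 1) / 0.5, 0)
  expect_equal(iemg(tri, t, 0.5, 1.5), 0.5, tolerance = 1e-6)
  # additivity over adjacent windows
  set.seed(2)
  env <- abs(rnorm(length(t)))
  expect_equal(iemg(env, t, 0.2, 0.9) + iemg(env, t, 0.9, 1.6),
               iemg(env, t, 0.2, 1.6), tolerance = 1e-9)
})

test_that("metabolic power uses the stated gas-exchange coefficients", {
  expect_equal(metabolic_power(0, 0), 0)
  expect_equal(metabolic_power(1, 0), 16.58)
  expect_equal(metabolic_power(4.0, 3.2), 80.752)
  expect_error(metabolic_power(-1, 0), ">= 0")
  # monotone in each argument
  expect_gt(metabolic_power(2, 1), metabolic_power(1.9, 1))
  expect_gt(metabolic_power(2, 1.1), metabolic_power(2, 1))
})

test_that("net metabolic rate subtracts the resting rate over the window", {
  walking <- data.frame(time_s = seq(0, 300, by = 3),
                        vo2_ml_s = 300 / 20.4135,
                        vco2_ml_s = 0.85 * 300 / 20.4135)
  resting <- data.frame(time_s = seq(0, 300, by = 3),
                        vo2_ml_s = 80 / 20.4135,
                        vco2_ml_s = 0.85 * 80 / 20.4135)
  out <- net_metabolic_rate(walking, resting, mass = 80)
  expect_equal(out$net, 2.75, tolerance = 1e-9)
  out0 <- net_metabolic_rate(walking, walking, mass = 80)
  expect_equal(out0$net, 0)
  short <- walking[walking$time_s < 100, ]
  expect_error(net_metabolic_rate(short, resting, 80), "shorter")
})

test_that("extracted net rate recovers the generator's target within noise", {
  tr <- fixture_trial()
  out <- net_metabolic_rate(tr$gases, tr$gases_resting, tr$subject$mass)
  # breath noise is 2% per breath; the window mean is much tighter
  expect_lt(abs(out$net - tr$true_values$net_met_rate), 0.1)
})
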