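test_that("event detection handles degenerate and clean inputs", {
  t <- seq(0, 2, by = 0.001)
  zero <- rep(0, length(t))
  expect_warning(ev <- detect_events(zero, zero, t), "no threshold")
  expect_equal(nrow(ev$left), 0)

  # clean square pulse: 0 -> 800 N at t = 1.000 s, off at 1.5 s
  pulse <- ifelse(t >= 1.000 & t < 1.5, 800, 0)
  ev <- suppressWarnings(detect_events(pulse, zero, t))
  expect_equal(nrow(ev$left), 1)
  expect_lt(abs(ev$left$strike - 1.000), 0.001)
  expect_lt(abs(ev$left$toeoff - 1.5), 0.001)
})

test_that("detected events match generator truth within one sample", {
  tr <- fixture_trial()
  ev <- detect_events(tr$grf$fz_l, tr$grf$fz_r, tr$grf$time_s)
  tv <- tr$true_values
  for (leg in c("left", "right")) {
    expect_gt(nrow(ev[[leg]]), 10)
    for (col in c("strike", "toeoff")) {
      err <- vapply(ev[[leg]][[col]],
                    function(s) min(abs(tv$events[[leg]][[col]] - s)),
                    numeric(1))
      expect_lt(max(err), 1 / tr$fs)
    }
  }
  # event counts differ by at most one between legs
  expect_lte(abs(nrow(ev$left) - nrow(ev$right)), 1)
  # every double-support window has positive length
  expect_true(all(ev$double_support$end > ev$double_support$start))
})

test_that("spatiotemporal parameters follow their defining formulas", {
  # stride length is belt speed times stride time by construction
  t <- seq(0, 6, by = 0.001)
  fz <- ifelse((t %% 1.12) < 0.69, 800, 0)
  fz2 <- ifelse(((t - 0.56) %% 1.12) < 0.69, 800, 0)
  mk <- data.frame(time_s = seq(0, 6, by = 0.01))
  mk$heel_l_x <- 0; mk$heel_l_y <- 0.06; mk$heel_l_z <- 0.03
  mk$heel_r_x <- 0; mk$heel_r_y <- -0.06; mk$heel_r_z <- 0.03
  ev <- detect_events(fz, fz2, t)
  spt <- spatiotemporal(ev, mk, belt_speed = 1.25)
  expect_equal(spt$strides$stride_time,
               rep(1.12, nrow(spt$strides)), tolerance = 2e-3)
  # the defining product holds exactly: 1.12 s at 1.25 m/s gives 1.40 m
  expect_equal(spt$strides$stride_length, 1.25 * spt$strides$stride_time)
  expect_equal(mean(spt$strides$stride_length), 1.40, tolerance = 3e-3)
  # constant 0.12 m mediolateral separation -> step width 0.12 m
  expect_equal(unique(round(spt$steps$step_width, 6)), 0.12)
})

test_that("extracted step lengths match generator truth within 1 mm", {
  tr <- fixture_trial()
  ex <- extract_trial(tr)
  agg <- aggregate(value ~ variable, ex$strides, mean)
  get <- function(v) agg$value[agg$variable == v]
  tv <- tr$true_values
  expect_lt(abs(get("spt_step_length_a2u") - tv$step_length_a2u), 1e-3)
  expect_lt(abs(get("spt_step_length_u2a") - tv$step_length_u2a), 1e-3)
  expect_lt(abs(get("spt_step_width") - tv$step_width), 1e-3)
  expect_lt(abs(get("spt_stride_length") - tv$stride_length), 2e-3)
})

test_that("COM velocity integrates Newton's second law per stride", {
  t <- seq(0, 4, by = 0.001)
  mass <- 80
  # zero net force: velocity is exactly the belt velocity
  grf <- cbind(x = 0 * t, y = 0 * t, z = rep(mass * 9.81, length(t)))
  v <- com_velocity(grf, t, mass, stride_times = c(0.5, 1.5, 2.5, 3.5))
  ok <- complete.cases(v)
  expect_equal(unname(v[ok, 1]), rep(1.25, sum(ok)), tolerance = 1e-10)
  expect_equal(unname(v[ok, 2]), rep(0, sum(ok)), tolerance = 1e-10)
  expect_equal(unname(v[ok, 3]), rep(0, sum(ok)), tolerance = 1e-10)

  # sinusoidal vertical load: analytic integral, strides on whole periods
  f <- 2; A <- 100
  grf2 <- cbind(x = 0 * t, y = 0 * t,
                z = mass * 9.81 + A * sin(2 * pi * f * (t - 0.5)))
  v2 <- com_velocity(grf2, t, mass, stride_times = c(0.5, 1.5, 2.5, 3.5))
  expected <- -A * cos(2 * pi * f * (t - 0.5)) / (2 * pi * f * mass)
  ok <- complete.cases(v2)
  expect_equal(v2[ok, 3], expected[ok], tolerance = 1e-4)
  expect_error(com_velocity(grf, t, 0, c(0.5, 1.5)), "mass")
})

test_that("COM velocity and transition work match generator truth within 2%", {
  tr <- fixture_trial()
  time <- tr$grf$time_s
  mass <- tr$subject$mass
  grf_l <- lowpass_filter(as.matrix(tr$grf[c("fx_l", "fy_l", "fz_l")]),
                          tr$fs, 7, 4)
  grf_r <- lowpass_filter(as.matrix(tr$grf[c("fx_r", "fy_r", "fz_r")]),
                          tr$fs, 7, 4)
  ev <- detect_events(tr$grf$fz_l, tr$grf$fz_r, time)
  aff <- tr$subject$affected_side
  v <- com_velocity(grf_l + grf_r, time, mass, ev[[aff]]$strike)
  tv <- tr$true_values

  ok <- complete.cases(v) & complete.cases(tv$com_velocity)
  rms_err <- sqrt(mean((v[ok, ] - tv$com_velocity[ok, ])^2))
  rms_sig <- sqrt(mean(tv$com_velocity[ok, ]^2))
  expect_lt(rms_err / rms_sig, 0.02)

  tw <- transition_work(grf_l, grf_r, v, time, ev, mass)
  side_of <- function(leg) ifelse(leg == aff, "affected", "unaffected")
  for (role in c("leading", "trailing")) {
    for (leg in c("left", "right")) {
      sel <- tw$leg == leg & tw$role == role
      for (sgn in c("positive", "negative")) {
        truth <- tv[[paste("work", role, side_of(leg), sgn, sep = "_")]]
        got <- abs(mean(tw[[paste0("work_", sgn, "_per_kg")]][sel]))
        if (truth > 0.01) {
          expect_lt(abs(got - truth) / truth, 0.02)
        } else {
          expect_lt(abs(got - truth), 0.01)
        }
      }
    }
  }
})

test_that("per-leg external power sums to total COM power exactly", {
  tr <- fixture_trial()
  time <- tr$grf$time_s
  grf_l <- as.matrix(tr$grf[c("fx_l", "fy_l", "fz_l")])
  grf_r <- as.matrix(tr$grf[c("fx_r", "fy_r", "fz_r")])
  ev <- detect_events(tr$grf$fz_l, tr$grf$fz_r, time)
  v <- com_velocity(grf_l + grf_r, time, tr$subject$mass,
                    ev$left$strike)
  ok <- complete.cases(v)
  p_l <- rowSums(grf_l[ok, ] * v[ok, ])
  p_r <- rowSums(grf_r[ok, ] * v[ok, ])
  p_tot <- rowSums((grf_l + grf_r)[ok, ] * v[ok, ])
  expect_equal(p_l + p_r, p_tot, tolerance = 1e-12)
})

test_that("transition work bookkeeping on constructed symmetric gait", {
  # mirror-symmetric double support built directly: the leading leg's power
  # is the time-reversed negative of the trailing leg's, so |leading
  # negative| equals trailing positive work
  t <- seq(0, 1, by = 0.001)
  mass <- 80
  ds <- c(0.4, 0.6)
  p_shape <- function(tt) sin(pi * (tt - ds[1]) / diff(ds))  # 0 at edges
  v <- cbind(x = rep(1.25, length(t)), y = 0, z = 0)
  f_trail <- cbind(x = 100 * p_shape(t) / 1.25, y = 0, z = 0)
  f_lead <- -f_trail
  # stance windows framing the double support
  ev <- structure(list(
    left = data.frame(strike = 0.4, toeoff = 0.95),
    right = data.frame(strike = 0.05, toeoff = 0.6),
    double_support = data.frame(start = 0.4, end = 0.6, leading = "left",
                                stringsAsFactors = FALSE)),
    class = "gait_events")
  tw <- transition_work(f_lead, f_trail, v, t, ev, mass)
  lead_neg <- tw$work_negative[tw$role == "leading"]
  trail_pos <- tw$work_positive[tw$role == "trailing"]
  expect_equal(abs(lead_neg), trail_pos, tolerance = 0.05 * trail_pos)
  # zero-force leg does zero work
  tw0 <- transition_work(f_lead * 0, f_trail, v, t, ev, mass)
  expect_equal(tw0$work_positive[tw0$leg == "left"], 0)
  expect_equal(tw0$work_negative[tw0$leg == "left"], 0)
  # signed work sums to the integral of total power (bookkeeping)
  p_tot <- rowSums((f_lead + f_trail) * v)
  total <- trapz_window(t, p_tot, ds[1], ds[2])
  per_leg <- sum(tw$work_positive + tw$work_negative)
  expect_equal(per_leg, total, tolerance = 1e-9)
})
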