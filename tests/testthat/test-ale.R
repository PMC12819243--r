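test_that("ALE of a constant model is identically zero", {
  X <- data.frame(x1 = rnorm(50), x2 = rnorm(50))
  cv <- ale_curve(function(M) rep(7, nrow(M)), X, "x1")
  expect_equal(cv$value, rep(0, length(cv$value)), tolerance = 1e-12)
  expect_warning(ale_curve(function(M) M$x2,
                           data.frame(x1 = rep(1, 30), x2 = rnorm(30)),
                           "x1"), "constant feature")
})

test_that("linear-model ALE has exactly the coefficient slope", {
  X <- correlated_pair(400, rho = 0.9, seed = 1)
  f <- function(M) 2 * M$x1 + 1 * M$x2
  cv <- ale_curve(f, X, "x1", n_intervals = 10)
  slopes <- diff(cv$value) / diff(cv$breaks)
  expect_equal(slopes, rep(2, length(slopes)), tolerance = 1e-6)
  # centering: sample-weighted mean of the curve is zero
  expect_lt(abs(mean(ale_at(cv, X$x1))), 1e-10)
})

test_that("additive-model ALE matches the centered component exactly at breakpoints", {
  X <- correlated_pair(400, rho = 0.9, seed = 2)
  g <- function(x) x^2 - 2 * x
  f <- function(M) g(M$x1) + 3 * M$x2
  cv <- ale_curve(f, X, "x1", n_intervals = 20)
  # accumulated differences of an additive model reproduce g up to a constant
  resid <- cv$value - g(cv$breaks)
  expect_lt(diff(range(resid)), 1e-9)
})

test_that("ALE on a fitted ensemble beats the partial-dependence baseline", {
  set.seed(4)
  X <- correlated_pair(400, rho = 0.9, seed = 4)
  g <- function(x) x^2 - 1
  y <- g(X$x1) + 3 * X$x2 + rnorm(400, 0, 0.05)
  fit <- bart_fit(X, y, bart_hyperparams(n_burn = 150, n_draws = 400,
                                         seed = 5))
  cv <- ale_curve(fit, X, "x1", n_intervals = 10, thin = 4)
  oracle <- function(x) g(x) - mean(g(X$x1))
  # errors weighted by how many sample rows each breakpoint represents
  w <- c(cv$count[1], cv$count) / sum(c(cv$count[1], cv$count))
  ale_err <- sqrt(sum(w * (cv$value - oracle(cv$breaks))^2))

  # partial dependence at the same breakpoints, brute force
  pd <- vapply(cv$breaks, function(z) {
    M <- X; M$x1 <- z
    mean(predict(fit, M, thin = 4))
  }, numeric(1))
  pd <- pd - mean(stats::approx(cv$breaks, pd, xout = X$x1, rule = 2)$y)
  pd_err <- sqrt(sum(w * (pd - oracle(cv$breaks))^2))

  expect_lt(ale_err, pd_err)      # correlation robustness, strict
  # and the curve tracks the marginal component closely
  expect_gt(cor(cv$value, oracle(cv$breaks)), 0.97)
})

test_that("bootstrap binning is consistent, linear and deterministic", {
  X <- correlated_pair(120, rho = 0.3, seed = 6)
  f <- function(M) 1.5 * M$x1 + 0.5 * M$x2
  # single replicate on the full table reproduces the plain curve
  b1 <- bootstrap_ale(f, X, "x1", sample_size = nrow(X), n_reps = 1,
                      n_bins = 10, seed = 1)
  cv <- ale_curve(f, X, "x1")
  # the pooled points of a full-table single replicate are the plain curve
  expect_equal(b1$points$value, ale_at(cv, b1$points$x), tolerance = 1e-9)

  # linear model: binned means collinear with bin centers
  b2 <- bootstrap_ale(f, X, "x1", sample_size = 40, n_reps = 20,
                      n_bins = 10, seed = 2)
  filled <- b2$bins$n > 0
  fit_r2 <- summary(lm(b2$bins$mean[filled] ~ b2$bins$bin_center[filled]))$r.squared
  expect_gte(fit_r2, 0.99)
  # counts partition the pooled points
  expect_equal(sum(b2$bins$n), nrow(b2$points))

  b3 <- bootstrap_ale(f, X, "x1", sample_size = 40, n_reps = 20,
                      n_bins = 10, seed = 2)
  expect_identical(b2$bins, b3$bins)
  expect_error(bootstrap_ale(f, X, "x1", sample_size = 500), "fewer rows")
})

test_that("effect size is the P90 - P10 spread of pooled curve values", {
  fake <- structure(list(points = data.frame(x = 0:10, value = 0:10)),
                    class = "ale_bootstrap")
  expect_equal(effect_size(fake), 8)   # brute force: 9 - 1
  const <- structure(list(points = data.frame(x = 1:5, value = rep(2, 5))),
                     class = "ale_bootstrap")
  expect_equal(effect_size(const), 0)
  # percentile homogeneity: scaling values by c scales the effect by |c|
  scaled <- structure(list(points = data.frame(x = 0:10, value = -3 * (0:10))),
                      class = "ale_bootstrap")
  expect_equal(effect_size(scaled), 3 * 8)
})

test_that("the effect report ranks, thresholds and reads direction", {
  mk <- function(vals, centers = seq_along(vals)) {
    structure(list(
      bins = data.frame(bin = seq_along(vals), bin_center = centers,
                        mean = vals, sd = 0, n = 10),
      points = data.frame(x = centers, value = vals),
      effect_size = as.numeric(quantile(vals, 0.9) - quantile(vals, 0.1))),
      class = "ale_bootstrap")
  }
  boots <- list(up = mk(c(-2, -1, 0, 1, 2)),       # increasing: decrease
                down = mk(c(2, 1, 0, -1, -2)),     # decreasing: increase
                tiny = mk(c(-0.01, 0, 0.01)))
  rep_ <- effect_report(boots, rmse_threshold = 0.5)
  expect_equal(rep_$feature[1:2], c("up", "down"))
  expect_true(all(rep_$retained[rep_$feature %in% c("up", "down")]))
  expect_false(rep_$retained[rep_$feature == "tiny"])
  expect_equal(rep_$direction[rep_$feature == "down"], "increase_to_reduce")
  expect_equal(rep_$direction[rep_$feature == "up"], "decrease_to_reduce")
  # every effect under threshold: empty retained set
  rep0 <- effect_report(boots["tiny"], rmse_threshold = 0.5)
  expect_equal(sum(rep0$retained), 0)
})
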