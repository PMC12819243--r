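make_linear_data <- function(n = 500, p = 10, noise = 0.01, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  list(X = X, y = 3 * X[, 1] + rnorm(n, 0, noise))
}

test_that("the sampler recovers a near-noiseless signal", {
  d <- make_linear_data()
  fit <- bart_fit(d$X, d$y, bart_hyperparams(seed = 42))
  expect_gte(pseudo_r2(fit), 0.95)
  # sum-of-trees centering: posterior mean of training fit near mean(y)
  expect_lt(abs(mean(fit$yhat_train) - mean(d$y)), 0.05 * sd(d$y))
})

test_that("pure-noise outcomes yield near-zero out-of-sample R2", {
  set.seed(3)
  X <- matrix(rnorm(300 * 5), 300, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- rnorm(300)
  tr <- 1:200
  fit <- bart_fit(X[tr, ], y[tr],
                  bart_hyperparams(n_burn = 100, n_draws = 300, seed = 4))
  oos <- pseudo_r2(predict(fit, X[-tr, ]), y = y[-tr])
  expect_lte(oos, 0.1)
})

test_that("fits are deterministic under a fixed seed", {
  d <- make_linear_data(n = 120, p = 4)
  hp <- bart_hyperparams(n_trees = 20, n_burn = 50, n_draws = 100, seed = 9)
  f1 <- bart_fit(d$X, d$y, hp)
  f2 <- bart_fit(d$X, d$y, hp)
  expect_identical(f1$yhat_train, f2$yhat_train)
  expect_identical(f1$sigma_draws, f2$sigma_draws)
  expect_identical(bart_vip(f1), bart_vip(f2))
})

test_that("prediction aligns columns by name and is row-consistent", {
  d <- make_linear_data(n = 150, p = 4)
  fit <- bart_fit(d$X, d$y,
                  bart_hyperparams(n_trees = 20, n_burn = 50, n_draws = 100,
                                   seed = 2))
  newX <- d$X[1:10, ]
  p1 <- predict(fit, newX)
  # permuted column order, same names: identical output
  p2 <- predict(fit, newX[, c(3, 1, 4, 2)])
  expect_identical(p1, p2)
  # duplicated row predicts identically
  p3 <- predict(fit, newX[c(1, 1), ])
  expect_equal(p3[1], p3[2])
  expect_error(predict(fit, newX[, 1:2]), "lacks")
})

test_that("fit metrics follow their closed forms", {
  # hand-computed pseudo-R2: yhat = {1,2}, y = {1,4}
  expect_equal(pseudo_r2(c(1, 2), y = c(1, 4)), 1 - 4 / 4.5,
               tolerance = 1e-12)
  expect_equal(pseudo_r2(c(1, 4), y = c(1, 4)), 1)
  expect_equal(pseudo_r2(c(2.5, 2.5), y = c(1, 4)), 0)
  expect_error(pseudo_r2(c(1, 2), y = c(2, 2)), "zero total")

  expect_equal(normalized_rmse(c(1, 4), y = c(1, 4)), 0)
  # constant error e on range R: 100 * e / R
  y <- c(0, 5, 10)
  expect_equal(normalized_rmse(y + 2, y = y), 100 * 2 / 10)
  # brute-force 4-point case
  y4 <- c(0.3, 1.1, 2.0, 2.9)
  p4 <- c(0.5, 1.0, 1.8, 3.1)
  expect_equal(normalized_rmse(p4, y = y4),
               sqrt(mean((p4 - y4)^2)) / (max(y4) - min(y4)) * 100)
  expect_error(normalized_rmse(c(1, 1), y = c(2, 2)), "degenerate")
})

test_that("variable inclusion proportions normalize and rank signals", {
  set.seed(5)
  n <- 300
  X <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("f", 1:10)))
  y <- 2 * X[, 1] + sin(2 * X[, 2]) + rnorm(n, 0, 0.1)
  fit <- bart_fit(X, y, bart_hyperparams(n_burn = 100, n_draws = 300,
                                         seed = 6))
  v <- bart_vip(fit)
  expect_equal(sum(v), 1, tolerance = 1e-9)
  expect_setequal(names(sort(v, decreasing = TRUE))[1:2], c("f1", "f2"))
})

test_that("degenerate training inputs are rejected", {
  X <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(bart_fit(X, rep(1, 30)), "constant")
  expect_error(bart_fit(X[1:10, ], rnorm(10)), "20 rows")
  Xna <- X; Xna[1, 1] <- NA
  expect_error(bart_fit(Xna, rnorm(30)), "missing")
})

test_that("cross-validation picks the plausible grid point", {
  d <- make_linear_data(n = 200, p = 5, noise = 0.05, seed = 8)
  grid1 <- list(bart_hyperparams(n_trees = 30, n_burn = 50, n_draws = 100))
  out1 <- bart_cv(d$X, d$y, grid = grid1, k = 3, seed = 1)
  expect_identical(out1$best, grid1[[1]])

  # adequate ensemble vs gross misfit (a single tree, heavy shrinkage)
  grid2 <- list(
    bart_hyperparams(n_trees = 50, k = 2, n_burn = 50, n_draws = 100),
    bart_hyperparams(n_trees = 1, k = 50, n_burn = 50, n_draws = 100))
  out2 <- bart_cv(d$X, d$y, grid = grid2, k = 3, seed = 1)
  expect_equal(out2$best$n_trees, 50L)
  expect_equal(nrow(out2$cv_table), 2)

  # same seed, same folds, same winner
  out3 <- bart_cv(d$X, d$y, grid = grid2, k = 3, seed = 1)
  expect_identical(out3$cv_table, out2$cv_table)

  subj <- rep(paste0("S", 1:10), each = 20)
  out4 <- bart_cv(d$X, d$y, grid = grid1, k = 5, subject = subj, seed = 2)
  expect_true(is.finite(out4$cv_table$mean_rmse))
})
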