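test_that("correlation pruning follows the threshold rule", {
  set.seed(1)
  n <- 100
  X <- data.frame(a = rnorm(n))
  X$b <- -X$a                       # |r| = 1
  X$c <- rnorm(n)
  d0 <- 0.75 * scale(X$a)[, 1] + sqrt(1 - 0.75^2) * rnorm(n)
  X$d <- d0                          # |r| ~ 0.75, below threshold

  out <- prune_correlated(X, pairs = list(c("a", "b"), c("a", "d")))
  expect_false("b" %in% names(out$X))     # second-listed member removed
  expect_true(all(c("a", "c", "d") %in% names(out$X)))
  expect_equal(out$removed$feature, "b")
  expect_warning(prune_correlated(X, pairs = list(c("a", "zzz"))), "absent")
})

test_that("registry-case pruning reduces 68 features to 62", {
  # feature table whose anatomical pairs are strongly anticorrelated,
  # as opposing joint-angle peak directions are
  subjects <- generate_cohort(10, seed = 2)
  gen <- generate_feature_table(subjects, seed = 2,
                                registry = build_registry("post_moment_removal"))
  tab <- gen$table
  for (p in anatomical_pairs()) tab[[p[2]]] <- -tab[[p[1]]] + rnorm(nrow(tab), 0, 0.05)
  X <- tab[, build_registry("post_moment_removal")$name]
  expect_equal(ncol(X), 68)
  out <- prune_correlated(X)
  expect_equal(ncol(out$X), 62)
  expect_setequal(names(out$X), build_registry("post_correlation_pruning")$name)
})

test_that("discovery-mode pruning removes the lower-VIP member", {
  set.seed(3)
  X <- data.frame(a = rnorm(80))
  X$b <- X$a + rnorm(80, 0, 0.1)
  X$c <- rnorm(80)
  vip <- c(a = 0.5, b = 0.3, c = 0.2)
  out <- prune_correlated(X, pairs = NULL, vip = vip)
  expect_false("b" %in% names(out$X))
  expect_true("a" %in% names(out$X))
})

test_that("averaged VIP is deterministic, normalized and signal-finding", {
  sc <- fixture_cohort()
  vip <- average_vip(sc$X, sc$y, n_models = 5, hp = selection_hp(),
                     seed = 100)
  expect_equal(sum(vip), 1, tolerance = 1e-9)
  expect_identical(vip, average_vip(sc$X, sc$y, n_models = 5,
                                    hp = selection_hp(), seed = 100))
  # all five active features inside the top 10 ranks
  expect_true(all(match(sc$active, names(vip)) <= 10))
})

test_that("the incremental curve plateaus once active features are in", {
  sc <- fixture_cohort()
  vip <- average_vip(sc$X, sc$y, n_models = 5, hp = selection_hp(),
                     seed = 100)
  curve <- incremental_curve(names(vip), sc$X, sc$y, hp = selection_hp(),
                             seed = 200, k_max = 12)
  expect_equal(nrow(curve), 12)
  # plateau: adding features beyond the active set gains little
  expect_gt(max(curve$pseudo_r2[6:12]), 0.9)
  expect_lt(max(curve$pseudo_r2[6:12]) - curve$pseudo_r2[6], 0.08)
})

test_that("select_k picks the smallest k within tolerance of the max", {
  curve <- data.frame(k = 1:4, pseudo_r2 = c(0.5, 0.9, 0.99, 1.0))
  expect_equal(select_k(curve, 0.01), 3)
  expect_equal(select_k(data.frame(k = 1:3, pseudo_r2 = rep(0.7, 3))), 1)
  # strictly increasing with no earlier value inside tolerance: k = P
  inc <- data.frame(k = 1:4, pseudo_r2 = c(0.2, 0.5, 0.8, 1.0))
  expect_equal(select_k(inc, 0.01), 4)
  # monotone in tolerance: larger tolerance never selects more features
  for (tol in c(0, 0.005, 0.02, 0.1, 0.5)) {
    expect_lte(select_k(curve, tol + 1e-3), select_k(curve, tol))
  }
  expect_error(select_k(curve[0, ]), "empty")
})
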