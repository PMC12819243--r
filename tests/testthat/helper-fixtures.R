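# shared fixtures, built once per test run

fixture_env <- new.env(parent = emptyenv())

# memoise expensive fixtures within one test session
fixture <- function(name, build) {
  if (!exists(name, envir = fixture_env)) {
    assign(name, build(), envir = fixture_env)
  }
  get(name, envir = fixture_env)
}

# a short synthetic trial shared by the mechanics/EMG oracle tests
fixture_trial <- function() {
  fixture("trial", function() {
    subj <- generate_cohort(1, seed = 3)
    cfgs <- prosthesis_configs()
    generate_trial_signals(subj, cfgs[cfgs$baseline, ], duration = 20,
                           seed = 11)
  })
}

# the standard modeling cohort at a fixed seed
fixture_cohort <- function() {
  fixture("cohort", function() standard_cohort(seed = 5))
}

# a well-converged ensemble on the standard cohort (shared by ALE tests)
fixture_fit <- function() {
  fixture("fit", function() {
    sc <- fixture_cohort()
    bart_fit(sc$X, sc$y,
             bart_hyperparams(n_trees = 200, n_burn = 250, n_draws = 1000,
                              seed = 7))
  })
}

# hyperparameters used for the fast selection-stage fits
selection_hp <- function(seed = NULL) {
  bart_hyperparams(n_trees = 50, n_burn = 100, n_draws = 200, seed = seed)
}

# count-weighted correlation (ALE points are displayed sized by bin count)
weighted_cor <- function(a, b, w) {
  stats::cov.wt(cbind(a, b), wt = w, cor = TRUE)$cor[1, 2]
}

# correlation-preserving bivariate normal sample
correlated_pair <- function(n, rho, seed = 1) {
  set.seed(seed)
  x1 <- rnorm(n)
  x2 <- rho * x1 + sqrt(1 - rho^2) * rnorm(n)
  data.frame(x1 = x1, x2 = x2)
}
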