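#' Hyperparameters for the sum-of-trees sampler
#'
#' Bundles the regularisation and MCMC settings of the BART ensemble. The
#' defaults are the canonical ones for this model family: `k` controls leaf
#' shrinkage through the leaf prior SD `0.5 / (k * sqrt(n_trees))` on the
#' internal \[-0.5, 0.5\] outcome scale, `(nu, q)` place the scaled inverse
#' chi-squared prior on the error variance so that `P(sigma < sigma_hat) = q`,
#' and `(alpha, beta)` give the depth-penalised split prior
#' `alpha * (1 + depth)^-beta`.
#'
#' @param n_trees number of trees in the ensemble.
#' @param k leaf-shrinkage parameter (larger shrinks leaf values harder).
#' @param nu,q error-variance prior degrees of freedom and quantile.
#' @param alpha,beta tree-depth prior parameters, `alpha` in (0,1), `beta >= 0`.
#' @param n_burn,n_draws burn-in and kept MCMC draws.
#' @param seed integer RNG seed giving a deterministic trace; `NULL` leaves the
#'   current RNG state untouched.
#' @return an object of class `bart_hyperparams`.
#' @export
bart_hyperparams <- function(n_trees = 50, k = 2, nu = 3, q = 0.9,
                             alpha = 0.95, beta = 2,
                             n_burn = 250, n_draws = 1000, seed = NULL) {
  stopifnot(n_trees >= 1, k > 0, nu > 0, q > 0, q < 1,
            alpha > 0, alpha < 1, beta >= 0, n_burn >= 0, n_draws >= 1)
  structure(list(n_trees = as.integer(n_trees), k = k, nu = nu, q = q,
                 alpha = alpha, beta = beta,
                 n_burn = as.integer(n_burn), n_draws = as.integer(n_draws),
                 seed = seed),
            class = "bart_hyperparams")
}

#' Default cross-validation grid
#'
#' The documented default grid of the cross-validated BART workflow: number of
#' trees in \{50, 200\}, leaf shrinkage `k` in \{2, 3, 5\} and error-variance
#' prior `(nu, q)` in \{(3, 0.9), (3, 0.99), (10, 0.75)\} — 18 combinations of
#' the four tuned hyperparameters.
#'
#' @param n_burn,n_draws MCMC settings applied to every grid point.
#' @return list of `bart_hyperparams`.
#' @export
default_bart_grid <- function(n_burn = 250, n_draws = 1000) {
  combos <- expand.grid(n_trees = c(50L, 200L), k = c(2, 3, 5),
                        nuq = 1:3, KEEP.OUT.ATTRS = FALSE)
  nuq <- list(c(3, 0.9), c(3, 0.99), c(10, 0.75))
  lapply(seq_len(nrow(combos)), function(i) {
    nq <- nuq[[combos$nuq[i]]]
    bart_hyperparams(n_trees = combos$n_trees[i], k = combos$k[i],
                     nu = nq[1], q = nq[2], n_burn = n_burn, n_draws = n_draws)
  })
}

as_feature_matrix <- function(X) {
  if (is.data.frame(X)) X <- data.matrix(X)
  if (!is.matrix(X) || !is.numeric(X)) stop("X must be a numeric matrix")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  X
}

# split-value candidates per column: midpoints of sorted unique values,
# evenly thinned to at most `numcut`
make_cutpoints <- function(X, numcut = 100L) {
  lapply(seq_len(ncol(X)), function(v) {
    u <- sort(unique(X[, v]))
    if (length(u) < 2) return(numeric(0))
    mids <- (u[-1] + u[-length(u)]) / 2
    if (length(mids) > numcut) {
      mids <- mids[unique(round(seq(1, length(mids), length.out = numcut)))]
    }
    mids
  })
}

#' Fit a Bayesian additive regression tree ensemble
#'
#' Metropolis-within-Gibbs backfitting: each sweep updates every tree with a
#' grow / prune / change proposal against the residual of the other trees,
#' then redraws leaf values and the error variance from their conjugate full
#' conditionals. The outcome is internally rescaled to \[-0.5, 0.5\].
#'
#' @param X numeric trial-by-feature matrix or data frame (no missing cells).
#' @param y numeric outcome vector.
#' @param hp a [bart_hyperparams()] object.
#' @param min_leaf smallest number of training rows allowed in a leaf.
#' @return an object of class `bart_model` with posterior train predictions,
#'   sigma draws (outcome units), per-draw variable-inclusion proportions and
#'   the serialized forest used by [predict.bart_model()].
#' @export
bart_fit <- function(X, y, hp = bart_hyperparams(), min_leaf = 5L) {
  X <- as_feature_matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  if (anyNA(X) || anyNA(y)) stop("missing cells are not allowed; impute first")
  if (nrow(X) < 20) stop("at least 20 rows are required")
  if (stats::sd(y) == 0) stop("constant outcome: zero variance")

  if (!is.null(hp$seed)) set.seed(hp$seed)

  ymin <- min(y); ymax <- max(y)
  ys <- (y - ymin) / (ymax - ymin) - 0.5
  sigma_hat <- stats::sd(ys)
  lambda <- sigma_hat^2 * stats::qchisq(1 - hp$q, hp$nu) / hp$nu
  tau2 <- (0.5 / (hp$k * sqrt(hp$n_trees)))^2
  cuts <- make_cutpoints(X)

  res <- .bart_mcmc(X, ys, cuts, hp$n_trees, tau2, hp$nu, lambda,
                    hp$alpha, hp$beta, hp$n_burn, hp$n_draws,
                    0.25, 0.25, as.integer(min_leaf), sigma_hat^2)

  scale_back <- function(z) (z + 0.5) * (ymax - ymin) + ymin
  yhat_train <- scale_back(colMeans(res$yhat_draws))

  structure(list(
    nodes = res$nodes,
    tree_offsets = res$tree_offsets,
    ntree = res$ntree,
    nkeep = res$nkeep,
    vip_draws = res$vip_draws,
    sigma_draws = res$sigma_draws * (ymax - ymin),
    yhat_train = yhat_train,
    y = y,
    y_range = c(ymin, ymax),
    feature_names = colnames(X),
    hp = hp), class = "bart_model")
}

#' Posterior predictions from a fitted ensemble
#'
#' @param object a `bart_model`.
#' @param newdata matrix or data frame whose columns cover the training
#'   features; columns are aligned by name, so order does not matter.
#' @param type `"mean"` for the posterior-mean prediction, `"draws"` for the
#'   per-draw matrix (kept draws by rows).
#' @param thin use every `thin`-th kept draw (prediction-heavy callers such as
#'   the ALE bootstrap thin the chain).
#' @param ... unused.
#' @return numeric vector (`"mean"`) or matrix (`"draws"`), outcome units.
#' @export
predict.bart_model <- function(object, newdata, type = c("mean", "draws"),
                               thin = 1L, ...) {
  type <- match.arg(type)
  newdata <- as_feature_matrix(newdata)
  missing_cols <- setdiff(object$feature_names, colnames(newdata))
  if (length(missing_cols) > 0) {
    stop("newdata lacks training features: ", paste(missing_cols, collapse = ", "))
  }
  newdata <- newdata[, object$feature_names, drop = FALSE]
  out <- .bart_predict_cpp(object$nodes, object$tree_offsets, object$ntree,
                           object$nkeep, newdata, type == "draws",
                           as.integer(thin))
  rng <- object$y_range
  (out + 0.5) * (rng[2] - rng[1]) + rng[1]
}

#' @export
print.bart_model <- function(x, ...) {
  cat(sprintf("BART ensemble: %d trees, %d kept draws, %d features\n",
              x$ntree, x$nkeep, length(x$feature_names)))
  cat(sprintf("  in-sample pseudo-R2 %.3f, normalized RMSE %.2f%%\n",
              pseudo_r2(x), normalized_rmse(x)))
  invisible(x)
}

resolve_predictions <- function(model, X, y) {
  if (inherits(model, "bart_model")) {
    if (is.null(X)) {
      list(yhat = model$yhat_train, y = if (is.null(y)) model$y else y)
    } else {
      list(yhat = predict(model, X), y = y)
    }
  } else {
    list(yhat = as.numeric(model), y = y)  # raw predictions
  }
}

#' Pseudo-R-squared of model predictions
#'
#' `1 - SSE/SST` with SST about the mean of `y` — the tree-ensemble analogue
#' of the coefficient of determination (in-sample convention when called
#' without `X`/`y`).
#'
#' @param model a `bart_model`, or a numeric vector of predictions.
#' @param X optional feature matrix to predict on (defaults to training fit).
#' @param y outcome vector (defaults to the training outcome).
#' @return unitless value, at most 1.
#' @export
pseudo_r2 <- function(model, X = NULL, y = NULL) {
  p <- resolve_predictions(model, X, y)
  if (length(p$y) < 2) stop("need at least 2 outcome values")
  sst <- sum((p$y - mean(p$y))^2)
  if (sst == 0) stop("zero total sum of squares")
  1 - sum((p$y - p$yhat)^2) / sst
}

#' Range-normalized RMSE of model predictions, in percent
#'
#' RMSE divided by the outcome range `max(y) - min(y)`, times 100.
#'
#' @inheritParams pseudo_r2
#' @return percentage (0 = perfect fit).
#' @export
normalized_rmse <- function(model, X = NULL, y = NULL) {
  p <- resolve_predictions(model, X, y)
  rng <- max(p$y) - min(p$y)
  if (rng <= 0) stop("degenerate outcome range")
  sqrt(mean((p$y - p$yhat)^2)) / rng * 100
}

#' Variable inclusion proportions
#'
#' The fraction of all tree split rules that use each feature, averaged over
#' kept posterior draws — and over models when a list of fits is given.
#'
#' @param model a `bart_model` or a list of them.
#' @return named numeric vector summing to 1.
#' @export
bart_vip <- function(model) {
  if (inherits(model, "bart_model")) model <- list(model)
  stopifnot(length(model) > 0)
  per_model <- vapply(model, function(m) colMeans(m$vip_draws),
                      numeric(length(model[[1]]$feature_names)))
  v <- rowMeans(matrix(per_model, ncol = length(model)))
  names(v) <- model[[1]]$feature_names
  v
}

#' Cross-validated hyperparameter selection
#'
#' k-fold cross-validation over a grid of hyperparameter settings, choosing
#' the setting with the lowest mean held-out RMSE. Folds are stratified by
#' subject when subject identifiers are supplied (trials cluster within
#' subject), otherwise rows are assigned at random. Ties are broken by fewer
#' trees, then grid order.
#'
#' @param X,y training data.
#' @param grid list of [bart_hyperparams()] settings (see [default_bart_grid()]).
#' @param k number of folds.
#' @param subject optional vector of per-row subject ids for stratified folds.
#' @param seed RNG seed for fold assignment and the per-fold fits.
#' @return list with `best` (the winning hyperparameters) and `cv_table`
#'   (data frame: grid point, mean held-out RMSE).
#' @export
bart_cv <- function(X, y, grid = default_bart_grid(), k = 5, subject = NULL,
                    seed = 1L) {
  stopifnot(k >= 2, length(grid) >= 1)
  X <- as_feature_matrix(X)
  n <- nrow(X)
  set.seed(seed)
  if (!is.null(subject)) {
    subj <- unique(subject)
    fold_of_subj <- sample(rep_len(seq_len(k), length(subj)))
    fold <- fold_of_subj[match(subject, subj)]
  } else {
    fold <- sample(rep_len(seq_len(k), n))
  }
  if (length(unique(fold)) < k) stop("a fold received no data")

  rmse <- matrix(NA_real_, nrow = length(grid), ncol = k)
  for (g in seq_along(grid)) {
    hp <- grid[[g]]
    for (f in seq_len(k)) {
      tr <- fold != f
      hp_f <- hp
      hp_f$seed <- seed + 1000L * g + f
      fit <- bart_fit(X[tr, , drop = FALSE], y[tr], hp_f)
      pred <- predict(fit, X[!tr, , drop = FALSE])
      rmse[g, f] <- sqrt(mean((y[!tr] - pred)^2))
    }
  }
  mean_rmse <- rowMeans(rmse)
  ord <- order(mean_rmse, vapply(grid, `[[`, integer(1), "n_trees"),
               seq_along(grid))
  best <- grid[[ord[1]]]
  cv_table <- data.frame(
    grid_point = seq_along(grid),
    n_trees = vapply(grid, `[[`, integer(1), "n_trees"),
    k = vapply(grid, `[[`, numeric(1), "k"),
    nu = vapply(grid, `[[`, numeric(1), "nu"),
    q = vapply(grid, `[[`, numeric(1), "q"),
    mean_rmse = mean_rmse)
  list(best = best, cv_table = cv_table)
}
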