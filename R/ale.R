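#' Accumulated local effects curve of one feature
#'
#' Standard first-order ALE: interval breakpoints at sample quantiles of the
#' feature; within each interval the model is evaluated at the interval's
#' upper and lower endpoint with all other features held at their observed
#' values, and the mean prediction difference is accumulated across
#' intervals. The curve is centered so its sample-weighted mean (each row
#' contributing its interpolated curve value) is zero. Local differencing
#' makes the estimate robust to correlation between features, unlike
#' marginal (partial-dependence) averaging.
#'
#' @param model a `bart_model`, or a function mapping a feature matrix to
#'   predictions.
#' @param X feature matrix or data frame (the sample the effects are
#'   accumulated over).
#' @param feature feature (column) name.
#' @param n_intervals requested interval count; capped at the number of
#'   distinct feature values minus one.
#' @param thin posterior thinning passed to [predict.bart_model()].
#' @return object of class `ale_curve`: `breaks` (breakpoints), `value`
#'   (centered accumulated effect at each breakpoint, outcome units),
#'   `count` (rows per interval), `centering` (the subtracted constant).
#' @export
ale_curve <- function(model, X, feature, n_intervals = 10, thin = 1L) {
  f <- if (inherits(model, "bart_model")) {
    function(M) predict(model, M, thin = thin)
  } else model
  X <- as.data.frame(X)
  if (!feature %in% names(X)) stop("unknown feature: ", feature)
  x <- X[[feature]]
  ux <- sort(unique(x))
  if (length(ux) < 2) {
    warning("constant feature: zero ALE curve")
    return(structure(list(feature = feature, breaks = ux,
                          value = 0, count = length(x), centering = 0),
                     class = "ale_curve"))
  }
  K <- min(n_intervals, length(ux) - 1)
  if (nrow(X) < K + 1) stop("need at least n_intervals + 1 rows")
  breaks <- unique(as.numeric(quantile(x, probs = seq(0, 1, length.out = K + 1),
                                       type = 7)))
  K <- length(breaks) - 1
  # interval k = (breaks[k], breaks[k+1]]; lowest values fall in interval 1
  idx <- findInterval(x, breaks, left.open = TRUE, rightmost.closed = TRUE)
  idx[idx < 1] <- 1

  delta <- numeric(K)
  count <- integer(K)
  for (k in seq_len(K)) {
    rows <- which(idx == k)
    count[k] <- length(rows)
    if (count[k] == 0) next
    hi <- X[rows, , drop = FALSE]; hi[[feature]] <- breaks[k + 1]
    lo <- X[rows, , drop = FALSE]; lo[[feature]] <- breaks[k]
    delta[k] <- mean(f(hi) - f(lo))
  }
  fj <- c(0, cumsum(delta))
  per_row <- stats::approx(breaks, fj, xout = x, rule = 2)$y
  centering <- mean(per_row)
  structure(list(feature = feature, breaks = breaks, value = fj - centering,
                 count = count, centering = centering),
            class = "ale_curve")
}

#' Evaluate an ALE curve at feature values
#'
#' Linear interpolation between breakpoints (constant beyond the range).
#'
#' @param curve an `ale_curve`.
#' @param x feature values.
#' @return curve values, outcome units.
#' @export
ale_at <- function(curve, x) {
  if (length(curve$breaks) < 2) return(rep(0, length(x)))
  stats::approx(curve$breaks, curve$value, xout = x, rule = 2)$y
}

#' Bootstrapped, binned ALE of one feature
#'
#' Replicates the trendline-bootstrap procedure: `n_reps` times, sample
#' `sample_size` rows without replacement, compute the ALE curve on the
#' subsample, and pool every replicate's (breakpoint, value) points. The
#' pooled points are binned into `n_bins` evenly spaced bins over the pooled
#' x-range; per-bin mean, SD and count summarize the trendline. Empty bins
#' are reported with count 0, never interpolated. The scalar effect size is
#' the 90th-minus-10th percentile spread of the pooled curve values.
#'
#' @param model `bart_model` or prediction function.
#' @param X feature matrix (the modeling trials).
#' @param feature feature name.
#' @param sample_size rows per replicate (default 40).
#' @param n_reps replicates (default 50).
#' @param n_bins even bins (default 10).
#' @param n_intervals ALE intervals inside each replicate (default 10).
#' @param seed RNG seed; bins are deterministic given the seed.
#' @param thin posterior thinning for prediction.
#' @return object of class `ale_bootstrap`: `bins` data frame
#'   (`bin_center`, `mean`, `sd`, `n`), `points` (pooled x/value),
#'   `effect_size` (outcome units).
#' @export
bootstrap_ale <- function(model, X, feature, sample_size = 40, n_reps = 50,
                          n_bins = 10, n_intervals = 10, seed = 1L,
                          thin = 1L) {
  X <- as.data.frame(X)
  if (nrow(X) < sample_size) stop("fewer rows than sample_size")
  if (n_bins < 1) stop("n_bins must be positive")
  set.seed(seed)
  pts_x <- list(); pts_v <- list()
  for (r in seq_len(n_reps)) {
    rows <- sample.int(nrow(X), sample_size)
    cv <- ale_curve(model, X[rows, , drop = FALSE], feature,
                    n_intervals = n_intervals, thin = thin)
    pts_x[[r]] <- cv$breaks
    pts_v[[r]] <- cv$value
  }
  px <- unlist(pts_x); pv <- unlist(pts_v)
  rng <- range(px)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)  # constant feature
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- findInterval(px, edges, rightmost.closed = TRUE)
  bins <- data.frame(
    bin = seq_len(n_bins),
    bin_center = (edges[-1] + edges[-(n_bins + 1)]) / 2,
    mean = NA_real_, sd = NA_real_, n = 0L)
  for (b in seq_len(n_bins)) {
    sel <- bin == b
    bins$n[b] <- sum(sel)
    if (bins$n[b] > 0) {
      bins$mean[b] <- mean(pv[sel])
      bins$sd[b] <- sd(pv[sel])
    }
  }
  structure(list(feature = feature, bins = bins,
                 points = data.frame(x = px, value = pv),
                 effect_size = effect_size_values(pv)),
            class = "ale_bootstrap")
}

effect_size_values <- function(values) {
  if (length(unique(values)) < 2) return(0)
  as.numeric(quantile(values, 0.9) - quantile(values, 0.1))
}

#' Scalar effect size of a bootstrapped ALE
#'
#' Difference between the 90th and 10th percentile of the pooled replicate
#' curve values (linear-interpolation percentile convention), in outcome
#' units.
#'
#' @param bootstrap an `ale_bootstrap`.
#' @return nonnegative effect size, W/kg for the metabolic outcome.
#' @export
effect_size <- function(bootstrap) {
  stopifnot(inherits(bootstrap, "ale_bootstrap"))
  effect_size_values(bootstrap$points$value)
}

#' Effect-size ranking report
#'
#' Ranks features by bootstrapped ALE effect size, retains those whose
#' effect exceeds the model's in-sample RMSE (outcome units), and summarizes
#' the direction of change that reduces the outcome from the first-vs-last
#' populated binned means.
#'
#' @param bootstraps named list of `ale_bootstrap` objects (one per
#'   feature).
#' @param rmse_threshold retention threshold, outcome units (the model's
#'   in-sample RMSE).
#' @return data frame sorted by descending effect size: `feature`,
#'   `effect_size`, `retained`, `direction` (`"increase_to_reduce"` /
#'   `"decrease_to_reduce"` / `"flat"`).
#' @export
effect_report <- function(bootstraps, rmse_threshold) {
  stopifnot(length(bootstraps) > 0, is.finite(rmse_threshold))
  rows <- lapply(names(bootstraps), function(nm) {
    b <- bootstraps[[nm]]
    if (!inherits(b, "ale_bootstrap")) stop("missing bootstrap for: ", nm)
    filled <- which(b$bins$n > 0)
    dirn <- if (length(filled) < 2) "flat" else {
      trend <- b$bins$mean[filled[length(filled)]] - b$bins$mean[filled[1]]
      if (trend < 0) "increase_to_reduce"
      else if (trend > 0) "decrease_to_reduce" else "flat"
    }
    data.frame(feature = nm, effect_size = b$effect_size,
               retained = b$effect_size > rmse_threshold,
               direction = dirn, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$effect_size), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rmse_threshold") <- rmse_threshold
  out
}

#' In-sample RMSE of a fitted ensemble, outcome units
#'
#' @param model a `bart_model`.
#' @return root mean squared error of the posterior-mean training
#'   predictions.
#' @export
model_rmse <- function(model) {
  stopifnot(inherits(model, "bart_model"))
  sqrt(mean((model$y - model$yhat_train)^2))
}
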