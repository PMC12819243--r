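#' Prune strongly correlated feature pairs
#'
#' Two modes. In replication mode (`pairs` supplied, the default anatomical
#' pairs), each listed pair whose Pearson correlation magnitude exceeds the
#' threshold loses its second-listed member — ankle eversion, hip external
#' rotation and hip adduction on both sides, reducing 68 features to 62. In
#' discovery mode (`pairs = NULL`) every feature pair over the threshold is
#' examined and the lower-VIP member removed (the later column when no VIP
#' ranking is given).
#'
#' @param X feature matrix or data frame (z-scored features).
#' @param threshold correlation magnitude threshold (default 0.8).
#' @param pairs list of 2-vectors of feature names, or `NULL` for discovery
#'   mode.
#' @param vip optional named VIP vector used to pick which member to drop in
#'   discovery mode.
#' @return list: `X` (reduced), `removed` (data frame `feature`, `partner`,
#'   `r`).
#' @export
prune_correlated <- function(X, threshold = 0.8, pairs = anatomical_pairs(),
                             vip = NULL) {
  X <- as.data.frame(X)
  removed <- list()
  drop_one <- function(a, b, r) {
    # pick the victim: second-listed in replication mode, lower VIP otherwise
    victim <- if (is.null(vip)) b else if (vip[a] >= vip[b]) b else a
    removed[[length(removed) + 1]] <<- data.frame(
      feature = victim, partner = setdiff(c(a, b), victim), r = r,
      stringsAsFactors = FALSE)
    victim
  }
  if (!is.null(pairs)) {
    for (p in pairs) {
      if (!all(p %in% names(X))) {
        warning("pair member absent, skipped: ", paste(p, collapse = " / "))
        next
      }
      r <- cor(X[[p[1]]], X[[p[2]]])
      if (abs(r) > threshold) X[[drop_one(p[1], p[2], r)]] <- NULL
    }
  } else {
    repeat {
      cm <- suppressWarnings(cor(X[vapply(X, is.numeric, logical(1))]))
      cm[!is.finite(cm)] <- 0  # constant columns correlate with nothing
      diag(cm) <- 0
      if (all(abs(cm) <= threshold)) break
      top <- which(abs(cm) == max(abs(cm)), arr.ind = TRUE)[1, ]
      if (abs(cm[top[1], top[2]]) <= threshold) break
      a <- rownames(cm)[top[1]]; b <- colnames(cm)[top[2]]
      X[[drop_one(a, b, cm[top[1], top[2]])]] <- NULL
    }
  }
  removed <- if (length(removed)) do.call(rbind, removed) else
    data.frame(feature = character(0), partner = character(0), r = numeric(0))
  list(X = X, removed = removed)
}

#' The anatomically paired angle features pruned in replication mode
#'
#' @return list of feature-name pairs; the second member of each pair is the
#'   removal candidate.
#' @export
anatomical_pairs <- function() {
  out <- list()
  for (side in c("affected", "unaffected")) {
    out <- c(out, list(
      c(paste0("angle_", side, "_ankle_inversion"),
        paste0("angle_", side, "_ankle_eversion")),
      c(paste0("angle_", side, "_hip_internal_rotation"),
        paste0("angle_", side, "_hip_external_rotation")),
      c(paste0("angle_", side, "_hip_abduction"),
        paste0("angle_", side, "_hip_adduction"))))
  }
  out
}

#' Average variable inclusion proportions over replicate fits
#'
#' Fits `n_models` ensembles with distinct derived seeds and averages each
#' feature's VIP, yielding a stable importance ranking.
#'
#' @param X,y training data.
#' @param n_models replicate count (default 20).
#' @param hp hyperparameters shared by the replicates.
#' @param seed base seed; replicate `i` uses `seed + i`.
#' @return named VIP vector (sums to 1), sorted decreasing.
#' @export
average_vip <- function(X, y, n_models = 20, hp = bart_hyperparams(),
                        seed = 1L) {
  stopifnot(n_models >= 1)
  fits <- vector("list", n_models)
  for (i in seq_len(n_models)) {
    hp_i <- hp
    hp_i$seed <- seed + i
    fits[[i]] <- tryCatch(bart_fit(X, y, hp_i), error = function(e) {
      stop("replicate ", i, " failed: ", conditionMessage(e))
    })
  }
  sort(bart_vip(fits), decreasing = TRUE)
}

#' Incremental feature-count performance curve
#'
#' One fit per k: the model on the top-k features of the ranking, recording
#' the in-sample pseudo-R-squared. The curve is reported as observed — dips
#' are not smoothed away.
#'
#' @param ranking feature names in decreasing importance order.
#' @param X,y training data.
#' @param hp hyperparameters for every fit.
#' @param seed base seed; the k-feature fit uses `seed + k`.
#' @param k_max largest feature count (default all ranked features).
#' @return object of class `selection_curve`: data frame `k`, `feature`
#'   (the added feature), `pseudo_r2`.
#' @export
incremental_curve <- function(ranking, X, y, hp = bart_hyperparams(),
                              seed = 1L, k_max = length(ranking)) {
  X <- as.data.frame(X)
  stopifnot(all(ranking %in% names(X)))
  r2 <- numeric(k_max)
  for (k in seq_len(k_max)) {
    hp_k <- hp
    hp_k$seed <- seed + k
    fit <- tryCatch(bart_fit(X[, ranking[seq_len(k)], drop = FALSE], y, hp_k),
                    error = function(e) {
                      stop("fit failed at k = ", k, ": ",
                           conditionMessage(e))
                    })
    r2[k] <- pseudo_r2(fit)
  }
  structure(data.frame(k = seq_len(k_max), feature = ranking[seq_len(k_max)],
                       pseudo_r2 = r2),
            class = c("selection_curve", "data.frame"))
}

#' Smallest feature count within tolerance of the best pseudo-R-squared
#'
#' Returns the smallest k whose pseudo-R-squared is within the tolerance of
#' the maximum across the curve. The tolerance is relative by default
#' (`value >= (1 - tolerance) * max`); an absolute reading
#' (`value >= max - tolerance`) is available since the two are nearly
#' identical when the maximum is close to 1.
#'
#' @param curve a `selection_curve` (or data frame with `k`, `pseudo_r2`).
#' @param tolerance proportion (default 0.01, i.e. within 1% of the
#'   maximum).
#' @param relative use the relative reading (default) or the absolute one.
#' @return the chosen k.
#' @export
select_k <- function(curve, tolerance = 0.01, relative = TRUE) {
  if (nrow(curve) == 0) stop("empty selection curve")
  best <- max(curve$pseudo_r2)
  cut <- if (relative) (1 - tolerance) * best else best - tolerance
  curve$k[which(curve$pseudo_r2 >= cut)[1]]
}
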