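#' Pipeline configuration
#'
#' Bundles every tunable of the channel-selection pipeline: feature
#' method, optional preprocessing, cluster count (fixed or grid-searched),
#' ranking algorithm and number of channels kept for classification.
#'
#' @param feature `"SP"` (AR band powers) or `"TDP"` (log-variance
#'   derivatives).
#' @param feature_spec an [ar_spec()] / [tdp_spec()]; default built from
#'   `feature`.
#' @param filter a [filter_spec()] or `NULL` to skip filtering.
#' @param window a [window_spec()] or `NULL` to use whole trials.
#' @param K fixed number of clusters for the feature compression.
#' @param k_grid optional integer grid; when given, `K` is selected per
#'   training set by [grid_search_k()] (nested, leak-free).
#' @param ranker `"RFS"`, `"RUFS"` or `"SSLSR"`.
#' @param ranker_cfg optional algorithm configuration
#'   ([rfs_config()], [rufs_config()], [sslsr_config()]).
#' @param n_channels number of top-ranked channels classified: an
#'   integer, `"all"`, or `"auto"` (argmax of the inner-CV accuracy
#'   curve, ties toward fewer channels).
#' @param seed integer seed governing every random element.
#' @return an `fccr_config`.
#' @export
fccr_config <- function(feature = c("SP", "TDP"), feature_spec = NULL,
                        filter = NULL, window = NULL,
                        K = 10L, k_grid = NULL,
                        ranker = c("RFS", "RUFS", "SSLSR"), ranker_cfg = NULL,
                        n_channels = "all", seed = 1L) {
  feature <- match.arg(feature)
  ranker <- match.arg(ranker)
  if (is.numeric(n_channels)) n_channels <- as.integer(n_channels)
  else if (!n_channels %in% c("all", "auto"))
    stop_fccr("fccr_config_error", "n_channels must be an integer, 'all' or 'auto'")
  structure(list(feature = feature, feature_spec = feature_spec,
                 filter = filter, window = window,
                 K = as.integer(K), k_grid = k_grid,
                 ranker = ranker, ranker_cfg = ranker_cfg,
                 n_channels = n_channels, seed = as.integer(seed)),
            class = "fccr_config")
}

preprocess_trialset <- function(ts, config) {
  if (!is.null(config$filter)) ts <- bandpass_filter(ts, config$filter)
  if (!is.null(config$window)) ts <- extract_window(ts, config$window)
  ts
}

rank_with <- function(ranker, X, Y, n_select, seed, cfg = NULL) {
  switch(ranker,
         RFS = rfs_rank(X, Y, cfg %||% rfs_config()),
         RUFS = rufs_rank(X, cfg %||% rufs_config(), L = ncol(Y), seed = seed),
         SSLSR = sslsr_rank(X, Y, cfg %||% sslsr_config(n_select = n_select)),
         stop_fccr("fccr_config_error", "unknown ranker '%s'", ranker))
}

# One training pass on already-extracted features: pool -> cluster ->
# compress -> rank -> LDA on original features of the selected channels.
# Test trials never enter; the cluster model serves the ranking only.
fit_fccr_stage <- function(ft, labels, train_idx, K, ranker, n_select,
                           seed, ranker_cfg = NULL) {
  dm <- dim(ft$values)
  C <- dm[2]
  if (is.character(n_select)) n_select <- C
  n_select <- min(n_select, C)
  pooled <- pool_features(ft, train_idx)
  km <- kmeans_fit(pooled$pool, K = K, seed = seed)
  Xt <- assign_signatures(km, ft, train_idx)
  cw <- rank_compressed(Xt, labels[train_idx], ranker, n_select,
                        seed = seed, cfg = ranker_cfg)
  selected <- sort(cw$ranking[seq_len(n_select)])   # ascending index order
  feats <- feature_matrix(ft, train_idx, selected)
  lda <- lda_fit(feats, labels[train_idx])
  list(cluster_model = km, compressed = Xt, weights = cw,
       ranking = cw$ranking, selected = selected, lda = lda,
       K = K, ranker = ranker, n_select = n_select)
}

# concatenated original feature vectors of the selected channels
# (channel-major blocks, channels in ascending index order)
feature_matrix <- function(ft, idx, channels) {
  dm <- dim(ft$values)
  out <- matrix(NA_real_, length(idx), length(channels) * dm[3])
  for (k in seq_along(channels)) {
    cols <- ((k - 1) * dm[3] + 1):(k * dm[3])
    out[, cols] <- ft$values[idx, channels[k], , drop = TRUE]
  }
  out
}

predict_fccr_stage <- function(fit, ft, idx) {
  lda_predict(fit$lda, feature_matrix(ft, idx, fit$selected))
}

#' Fit the feature-compressing channel-ranking model
#'
#' End-to-end training on a set of labelled trials: optional FIR bandpass
#' and analysis-window preprocessing, per-channel feature extraction,
#' pooling and k-means compression into integer cluster signatures,
#' channel ranking by the configured row-sparse selection algorithm, and
#' a regularized LDA classifier on the original features of the selected
#' channels. Returns a fitted model that can classify new trials.
#'
#' @param ts a [trial_set()].
#' @param config an [fccr_config()]; individual arguments below override
#'   its fields when supplied.
#' @param ... passed to [fccr_config()] when `config` is missing.
#' @return an object of class `fccr` with components `config`,
#'   `ranking`, `selected`, `channel_weights`, `cluster_model`, `lda`,
#'   and the channel names.
#' @examples
#' ts <- generate_synthetic(synth_spec(C = 6, informative = 1:2,
#'                                     n_per_class = 12, M = 120, seed = 1))
#' fit <- fccr(ts, config = fccr_config(K = 5, ranker = "RFS",
#'                                      n_channels = 2, seed = 1))
#' fit
#' coef(fit)
#' @export
fccr <- function(ts, config = fccr_config(...), ...) {
  stopifnot(inherits(ts, "trial_set"))
  pts <- preprocess_trialset(ts, config)
  ft <- extract_features(pts, config$feature, config$feature_spec)
  all_idx <- seq_len(n_trials(pts))
  K <- config$K
  if (!is.null(config$k_grid)) {
    gs <- grid_search_k(ft, pts$labels, grid = config$k_grid,
                        ranker = config$ranker,
                        n_select = if (is.numeric(config$n_channels))
                          config$n_channels else NULL,
                        seed = config$seed)
    K <- gs$K
  }
  n_sel <- resolve_n_channels(config, ft, pts$labels, K)
  fit <- fit_fccr_stage(ft, pts$labels, all_idx, K = K,
                        ranker = config$ranker, n_select = n_sel,
                        seed = config$seed, ranker_cfg = config$ranker_cfg)
  structure(list(config = config, K = K,
                 channel_names = ts$channel_names,
                 ranking = fit$ranking, selected = fit$selected,
                 channel_weights = fit$weights,
                 cluster_model = fit$cluster_model, lda = fit$lda,
                 n_classes = pts$n_classes,
                 training_accuracy = accuracy(
                   pts$labels, predict_fccr_stage(fit, ft, all_idx))),
            class = "fccr")
}

# "auto" channel count: argmax of the inner 5-fold CV accuracy curve,
# ties toward fewer channels; integer / "all" pass through.
resolve_n_channels <- function(config, ft, labels, K) {
  C <- dim(ft$values)[2]
  if (is.numeric(config$n_channels)) return(min(config$n_channels, C))
  if (identical(config$n_channels, "all")) return(C)
  folds <- make_cv_folds(length(labels), labels, n_folds = 5L,
                         n_repeats = 1L, seed = config$seed)[[1]]
  acc <- matrix(NA_real_, 5, C)
  for (f in 1:5) {
    tr <- which(folds != f); te <- which(folds == f)
    fit <- fit_fccr_stage(ft, labels, tr, K = min(K, length(tr)),
                          ranker = config$ranker, n_select = C,
                          seed = config$seed, ranker_cfg = config$ranker_cfg)
    for (n in seq_len(C)) {
      sel <- sort(fit$ranking[seq_len(n)])
      lda <- lda_fit(feature_matrix(ft, tr, sel), labels[tr])
      acc[f, n] <- accuracy(labels[te],
                            lda_predict(lda, feature_matrix(ft, te, sel)))
    }
  }
  curve <- colMeans(acc)
  which.max(curve)   # first max -> fewest channels
}

#' @export
print.fccr <- function(x, ...) {
  cat(sprintf("<fccr> %s features, %s ranking, K = %d clusters\n",
              x$config$feature, x$config$ranker, x$K))
  cat(sprintf("  selected %d/%d channels: %s\n",
              length(x$selected), length(x$ranking),
              paste(x$channel_names[x$selected], collapse = ", ")))
  cat(sprintf("  training accuracy: %.1f%%\n", x$training_accuracy))
  invisible(x)
}

#' @export
summary.fccr <- function(object, ...) {
  print(object)
  w <- coef(object)
  cat("\nChannel weights ||W(i,:)||_2 (ranked):\n")
  print(round(w[object$ranking], 4))
  tr <- object$channel_weights$objective_trace
  if (length(tr))
    cat(sprintf("\nRanker objective: %.6g -> %.6g in %d iterations\n",
                tr[1], tr[length(tr)], length(tr)))
  invisible(object)
}

#' Per-channel weights of a fitted model
#' @param object an `fccr` fit.
#' @param ... unused.
#' @return named numeric vector `||W(i,:)||_2` per channel.
#' @export
coef.fccr <- function(object, ...) {
  stats::setNames(object$channel_weights$weights, object$channel_names)
}

#' Classify new trials with a fitted model
#'
#' Applies the stored preprocessing and feature extraction to `newdata`
#' and classifies the original features of the selected channels with the
#' fitted LDA. The cluster model is not applied to new trials; it serves
#' channel ranking only.
#'
#' @param object an `fccr` fit.
#' @param newdata a `trial_set` with the same channels and sampling rate.
#' @param ... unused.
#' @return integer vector of predicted labels.
#' @export
predict.fccr <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "trial_set"))
  pts <- preprocess_trialset(newdata, object$config)
  ft <- extract_features(pts, object$config$feature, object$config$feature_spec)
  lda_predict(object$lda,
              feature_matrix(ft, seq_len(n_trials(pts)), object$selected))
}

#' Plot a fitted model's channel weights and convergence
#'
#' Left panel: per-channel weights with the selected channels
#' highlighted. Right panel (when a trace exists): the ranker's objective
#' per iteration.
#'
#' @param x an `fccr` fit.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.fccr <- function(x, ...) {
  tr <- x$channel_weights$objective_trace
  op <- graphics::par(mfrow = c(1, if (length(tr) > 1) 2 else 1))
  on.exit(graphics::par(op))
  cols <- ifelse(seq_along(x$ranking) %in% x$selected, "firebrick", "grey70")
  graphics::barplot(coef(x), col = cols, las = 2,
                    ylab = "||W(i,:)||_2", main = paste(x$config$ranker,
                                                       "channel weights"), ...)
  if (length(tr) > 1)
    graphics::plot(tr, type = "b", pch = 20, xlab = "iteration",
                   ylab = "objective", main = "ranker convergence")
  invisible(x)
}
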