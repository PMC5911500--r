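#' Repeated stratified cross-validation plan
#'
#' The benchmark protocol: five repeats of stratified 5-fold partitioning
#' (25 train/test splits). Fold assignments are a pure function of
#' `(N, labels, seed)`, so competing configurations sharing a seed see
#' identical splits.
#'
#' @param n_folds folds per repeat (default 5).
#' @param n_repeats repeats (default 5).
#' @param seed integer seed.
#' @return a `cv_plan`.
#' @export
cv_plan <- function(n_folds = 5L, n_repeats = 5L, seed = 1L) {
  if (n_folds < 2) stop_fccr("fccr_config_error", "need at least 2 folds")
  structure(list(n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats),
                 seed = as.integer(seed)),
            class = "cv_plan")
}

#' Stratified fold assignments
#'
#' Within each class, trial indices are shuffled (seeded) and dealt
#' round-robin over folds, so each fold contains every class where counts
#' permit. Depends only on `(N, labels, n_folds, n_repeats, seed)`.
#'
#' @param N number of trials.
#' @param labels class labels.
#' @param n_folds,n_repeats,seed see [cv_plan()].
#' @return list of `n_repeats` integer vectors of fold ids in `1..n_folds`.
#' @export
make_cv_folds <- function(N, labels, n_folds = 5L, n_repeats = 5L, seed = 1L) {
  labels <- as.integer(labels)
  if (length(labels) != N)
    stop_fccr("fccr_shape_error", "length(labels) != N")
  with_seed(seed, {
    lapply(seq_len(n_repeats), function(r) {
      fold <- integer(N)
      for (cl in sort(unique(labels))) {
        idx <- which(labels == cl)
        idx <- idx[sample.int(length(idx))]
        fold[idx] <- rep_len(seq_len(n_folds), length(idx))
      }
      fold
    })
  })
}

#' Cross-validated evaluation of the full pipeline
#'
#' For each of the plan's train/test splits, runs the complete training
#' path on the training trials only — feature pooling, k-means
#' compression, channel ranking and LDA fitting — then classifies the
#' held-out fold. Feature extraction is per-trial, so it is computed once
#' up front without information leak. Test-fold trials never touch the
#' cluster model or the ranker.
#'
#' @param ts a `trial_set`.
#' @param config an [fccr_config()].
#' @param plan a [cv_plan()].
#' @return an `fccr_cv` report: per-fold metrics, mean and sd across
#'   folds, and per-fold fitted summaries (ranking, weights, LDA means)
#'   for reproducibility checks.
#' @export
cross_validate <- function(ts, config = fccr_config(), plan = cv_plan()) {
  pts <- preprocess_trialset(ts, config)
  ft <- extract_features(pts, config$feature, config$feature_spec)
  labels <- pts$labels
  N <- n_trials(pts)
  folds <- make_cv_folds(N, labels, plan$n_folds, plan$n_repeats, plan$seed)
  rows <- list(); fits <- list()
  for (r in seq_len(plan$n_repeats)) {
    for (f in seq_len(plan$n_folds)) {
      tr <- which(folds[[r]] != f)
      te <- which(folds[[r]] == f)
      if (length(unique(labels[te])) < length(unique(labels)))
        stop_fccr("fccr_stratification_error",
                  "fold %d of repeat %d lacks a class", f, r)
      K <- config$K
      if (!is.null(config$k_grid)) {
        ft_tr <- ft
        ft_tr$values <- ft$values[tr, , , drop = FALSE]
        K <- grid_search_k(ft_tr, labels[tr], grid = config$k_grid,
                           ranker = config$ranker,
                           seed = config$seed + r)$K
      }
      n_sel <- if (is.numeric(config$n_channels)) config$n_channels
               else dim(ft$values)[2]
      fit <- fit_fccr_stage(ft, labels, tr, K = min(K, length(tr)),
                            ranker = config$ranker, n_select = n_sel,
                            seed = config$seed + 1000L * r + f,
                            ranker_cfg = config$ranker_cfg)
      pred <- predict_fccr_stage(fit, ft, te)
      prf <- suppressWarnings(precision_recall_f1(labels[te], pred))
      rows[[length(rows) + 1]] <- data.frame(
        repeat_id = r, fold = f,
        accuracy = accuracy(labels[te], pred),
        precision = prf$precision, recall = prf$recall, f1 = prf$f1,
        K = fit$K)
      fits[[length(fits) + 1]] <- list(
        repeat_id = r, fold = f, ranking = fit$ranking,
        weights = fit$weights$weights, lda_means = fit$lda$means,
        selected = fit$selected)
    }
  }
  per_fold <- do.call(rbind, rows)
  metrics <- c("accuracy", "precision", "recall", "f1")
  structure(list(per_fold = per_fold,
                 mean = vapply(per_fold[metrics], mean, 0),
                 sd = vapply(per_fold[metrics], stats::sd, 0),
                 folds = folds, fits = fits,
                 config = config, plan = plan),
            class = "fccr_cv")
}

#' @export
print.fccr_cv <- function(x, ...) {
  cat(sprintf("<fccr_cv> %s/%s, %d folds\n", x$config$feature,
              x$config$ranker, nrow(x$per_fold)))
  for (m in names(x$mean))
    cat(sprintf("  %-9s %6.2f +/- %.2f %%\n", m, x$mean[m], x$sd[m]))
  invisible(x)
}

#' @export
summary.fccr_cv <- function(object, ...) {
  print(object)
  cat("\nPer-repeat mean accuracy:\n")
  print(round(tapply(object$per_fold$accuracy, object$per_fold$repeat_id, mean), 2))
  invisible(object)
}

#' Accuracy against the number of selected channels
#'
#' Runs one cross-validation in which each fold is ranked once and then
#' classified with the top-`n` channels for every `n` in `n_range`
#' (channels concatenated in ascending index order, so `n = C` reproduces
#' the all-channels result exactly).
#'
#' @param ts a `trial_set`.
#' @param config an [fccr_config()].
#' @param plan a [cv_plan()].
#' @param n_range channel counts to evaluate (default `1:C`).
#' @return an `fccr_sweep`: data.frame `curve` with columns `n`,
#'   `accuracy_mean`, `accuracy_sd`, `f1_mean`, `f1_sd`, and `best_n`
#'   (argmax accuracy, ties toward fewer channels).
#' @export
channel_sweep <- function(ts, config = fccr_config(), plan = cv_plan(),
                          n_range = NULL) {
  pts <- preprocess_trialset(ts, config)
  ft <- extract_features(pts, config$feature, config$feature_spec)
  C <- dim(ft$values)[2]
  if (is.null(n_range)) n_range <- seq_len(C)
  if (any(n_range < 1) || any(n_range > C))
    stop_fccr("fccr_bounds_error", "n_range outside 1..%d", C)
  labels <- pts$labels
  folds <- make_cv_folds(n_trials(pts), labels, plan$n_folds,
                         plan$n_repeats, plan$seed)
  acc <- matrix(NA_real_, 0, length(n_range))
  f1m <- matrix(NA_real_, 0, length(n_range))
  for (r in seq_len(plan$n_repeats)) {
    for (f in seq_len(plan$n_folds)) {
      tr <- which(folds[[r]] != f); te <- which(folds[[r]] == f)
      fit <- fit_fccr_stage(ft, labels, tr, K = min(config$K, length(tr)),
                            ranker = config$ranker, n_select = C,
                            seed = config$seed + 1000L * r + f,
                            ranker_cfg = config$ranker_cfg)
      arow <- numeric(length(n_range)); frow <- numeric(length(n_range))
      for (k in seq_along(n_range)) {
        sel <- sort(fit$ranking[seq_len(n_range[k])])
        lda <- lda_fit(feature_matrix(ft, tr, sel), labels[tr])
        pred <- lda_predict(lda, feature_matrix(ft, te, sel))
        arow[k] <- accuracy(labels[te], pred)
        frow[k] <- suppressWarnings(precision_recall_f1(labels[te], pred))$f1
      }
      acc <- rbind(acc, arow); f1m <- rbind(f1m, frow)
    }
  }
  curve <- data.frame(n = n_range,
                      accuracy_mean = colMeans(acc),
                      accuracy_sd = apply(acc, 2, stats::sd),
                      f1_mean = colMeans(f1m),
                      f1_sd = apply(f1m, 2, stats::sd))
  structure(list(curve = curve,
                 best_n = n_range[which.max(curve$accuracy_mean)],
                 config = config, plan = plan),
            class = "fccr_sweep")
}

#' @export
print.fccr_sweep <- function(x, ...) {
  cat(sprintf("<fccr_sweep> %d channel counts; best n = %d (%.2f%%)\n",
              nrow(x$curve), x$best_n,
              x$curve$accuracy_mean[x$curve$n == x$best_n]))
  invisible(x)
}

#' @export
plot.fccr_sweep <- function(x, ...) {
  graphics::plot(x$curve$n, x$curve$accuracy_mean, type = "b", pch = 20,
                 xlab = "number of selected channels",
                 ylab = "mean CV accuracy (%)",
                 main = paste(x$config$ranker, "channel sweep"), ...)
  graphics::abline(v = x$best_n, lty = 2, col = "firebrick")
  invisible(x)
}

#' Compare ranking algorithms on identical folds
#'
#' Runs [cross_validate()] for each configuration; all configurations
#' must share the same CV seed so fold assignments (a pure function of
#' the labels and the seed) are identical across methods.
#'
#' @param ts a `trial_set`.
#' @param configs named list of [fccr_config()]s.
#' @param plan a [cv_plan()].
#' @return an `fccr_comparison`: the per-method reports plus a summary
#'   table of mean +/- sd accuracy and F1.
#' @export
compare_rankers <- function(ts, configs, plan = cv_plan()) {
  if (is.null(names(configs)))
    names(configs) <- vapply(configs, function(cf) cf$ranker, "")
  seeds <- vapply(configs, function(cf) cf$seed, 0L)
  if (length(unique(seeds)) != 1)
    stop_fccr("fccr_protocol_error",
              "all configurations must share one seed (got %s)",
              paste(seeds, collapse = ", "))
  reports <- lapply(configs, function(cf) cross_validate(ts, cf, plan))
  tab <- do.call(rbind, lapply(names(reports), function(nm) {
    rp <- reports[[nm]]
    data.frame(method = nm,
               accuracy_mean = rp$mean["accuracy"], accuracy_sd = rp$sd["accuracy"],
               f1_mean = rp$mean["f1"], f1_sd = rp$sd["f1"],
               row.names = NULL)
  }))
  structure(list(reports = reports, table = tab, plan = plan),
            class = "fccr_comparison")
}

#' @export
print.fccr_comparison <- function(x, ...) {
  cat("<fccr_comparison>\n")
  print(x$table, digits = 4)
  invisible(x)
}

#' Export a cross-validation report
#'
#' Writes the per-fold table as CSV and the aggregate report (mean, sd,
#' configuration echo) as JSON.
#'
#' @param cv an `fccr_cv`.
#' @param path_csv,path_json output paths (`NULL` skips either).
#' @return invisibly, the JSON-able report list.
#' @export
export_report <- function(cv, path_csv = NULL, path_json = NULL) {
  rep <- list(schema = "fccr-report-v1",
              feature = cv$config$feature, ranker = cv$config$ranker,
              n_folds = nrow(cv$per_fold),
              mean = as.list(cv$mean), sd = as.list(cv$sd))
  if (!is.null(path_csv))
    utils::write.csv(cv$per_fold, path_csv, row.names = FALSE)
  if (!is.null(path_json))
    jsonlite::write_json(rep, path_json, auto_unbox = TRUE, digits = NA)
  invisible(rep)
}
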