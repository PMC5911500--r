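#' Recovery and accuracy benchmark on synthetic motor-imagery EEG
#'
#' Runs the full pipeline on one draw of the synthetic generator and
#' measures, for each requested ranking algorithm, (i) the
#' informative-channel recovery score of the ranking fitted on all
#' trials, and (ii) the cross-validated accuracy when only the top
#' `n_select` ranked channels are classified. All rankers share the same
#' folds and, within each fold, the same fitted cluster compression
#' (identical upstream stages), mirroring a fair method comparison.
#'
#' @param spec a [synth_spec()]; its seed drives the generator, the fold
#'   assignment and every fitted stage.
#' @param K number of clusters for the compression stage.
#' @param n_select channels kept for classification (default: the number
#'   of informative channels in `spec`).
#' @param plan a [cv_plan()]; defaults to the 5x5 protocol seeded from
#'   `spec$seed`.
#' @param rankers ranking algorithms to evaluate.
#' @return list with `recovery` and `cv_accuracy` (named per ranker),
#'   `per_fold` accuracy data.frame, and `rankings` (full-data ranking
#'   per ranker).
#' @export
benchmark_recovery <- function(spec = synth_spec(), K = 10L,
                               n_select = length(spec$informative),
                               plan = cv_plan(seed = spec$seed),
                               rankers = c("RFS", "RUFS", "SSLSR")) {
  ts <- generate_synthetic(spec)
  ft <- extract_features(ts, "SP")
  N <- n_trials(ts)
  labels <- ts$labels
  L <- length(unique(labels))

  # full-data ranking -> recovery score per ranker (shared compression)
  km_all <- kmeans_fit(pool_features(ft, seq_len(N))$pool, K = K,
                       seed = spec$seed)
  Xt_all <- assign_signatures(km_all, ft)
  recovery <- vapply(rankers, function(rk) {
    cw <- rank_compressed(Xt_all, labels, rk, n_select, seed = spec$seed)
    ground_truth_recovery_score(cw$ranking, spec)
  }, 0)

  folds <- make_cv_folds(N, labels, plan$n_folds, plan$n_repeats, plan$seed)
  rows <- list()
  for (r in seq_len(plan$n_repeats)) {
    for (f in seq_len(plan$n_folds)) {
      tr <- which(folds[[r]] != f); te <- which(folds[[r]] == f)
      km <- kmeans_fit(pool_features(ft, tr)$pool, K = min(K, length(tr)),
                       seed = spec$seed + 1000L * r + f)
      Xt <- assign_signatures(km, ft, tr)
      for (rk in rankers) {
        cw <- rank_compressed(Xt, labels[tr], rk, n_select,
                              seed = spec$seed + 1000L * r + f)
        sel <- sort(cw$ranking[seq_len(n_select)])
        lda <- lda_fit(feature_matrix(ft, tr, sel), labels[tr])
        pred <- lda_predict(lda, feature_matrix(ft, te, sel))
        rows[[length(rows) + 1]] <- data.frame(
          ranker = rk, repeat_id = r, fold = f,
          accuracy = accuracy(labels[te], pred))
      }
    }
  }
  per_fold <- do.call(rbind, rows)
  acc <- vapply(rankers, function(rk)
    mean(per_fold$accuracy[per_fold$ranker == rk]), 0)
  rankings <- lapply(stats::setNames(rankers, rankers), function(rk)
    rank_compressed(Xt_all, labels, rk, n_select, seed = spec$seed)$ranking)
  list(recovery = recovery, cv_accuracy = acc, per_fold = per_fold,
       rankings = rankings)
}

# centering + ranking shared by the pipeline and the benchmark:
# signatures are ordinal codes, so columns are centered (and the label
# indicator too for the supervised rankers) before the intercept-free
# regressions.
rank_compressed <- function(Xt, labels_train, ranker, n_select, seed,
                            cfg = NULL) {
  Xc <- scale(unclass_matrix(Xt), center = TRUE, scale = FALSE)
  L <- length(unique(labels_train))
  Y <- make_label_indicator(labels_train, L)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  suppressWarnings(
    rank_with(ranker, Xc, Yc, n_select = n_select, seed = seed, cfg = cfg))
}
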