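#' Pool training-trial feature vectors across trials and channels
#'
#' Collects every (trial, channel) feature vector of the training trials
#' into one pool, discarding the trial/channel structure (but returning an
#' invertible coordinate map so each pooled row can be traced back).
#'
#' @param ft a `feature_tensor`.
#' @param training_idx non-empty trial indices.
#' @return list with `pool` (matrix `(N_bar*C) x d`) and `coords`
#'   (data.frame with columns `trial`, `channel`, row i describing pool
#'   row i).
#' @export
pool_features <- function(ft, training_idx) {
  dm <- dim(ft$values)
  training_idx <- as.integer(training_idx)
  if (length(training_idx) == 0)
    stop_fccr("fccr_precondition_error", "training index set is empty")
  if (any(training_idx < 1) || any(training_idx > dm[1]))
    stop_fccr("fccr_bounds_error", "training indices out of 1..%d", dm[1])
  nb <- length(training_idx); C <- dm[2]
  pool <- matrix(NA_real_, nb * C, dm[3])
  coords <- data.frame(trial = rep(training_idx, each = C),
                       channel = rep(seq_len(C), nb))
  r <- 1L
  for (i in training_idx) {
    pool[r:(r + C - 1), ] <- ft$values[i, , ]
    r <- r + C
  }
  list(pool = pool, coords = coords)
}

# squared Euclidean distances between rows of x (n x d) and rows of cen (k x d)
sqdist_to_centers <- function(x, cen) {
  d2 <- rowSums(x * x) - 2 * tcrossprod(x, cen)   # vector recycles down columns
  sweep(d2, 2, rowSums(cen * cen), "+")           # may go slightly negative
}

# numerical floor for the (possibly -1e-12-ish) squared distances
clamp0 <- function(v) {
  v[v < 0] <- 0
  v
}

kmeanspp_init <- function(x, K) {
  n <- nrow(x)
  centers <- matrix(NA_real_, K, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  if (K > 1) {
    d2 <- sqdist_to_centers(x, centers[1, , drop = FALSE])[, 1]
    for (k in 2:K) {
      d2 <- clamp0(d2)
      p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[k, ] <- x[sample.int(n, 1, prob = p), ]
      d2 <- pmin(d2, sqdist_to_centers(x, centers[k, , drop = FALSE])[, 1])
    }
  }
  centers
}

lloyd_once <- function(x, centers) {
  K <- nrow(centers)
  wcss_trace <- numeric(0)
  assign <- rep(0L, nrow(x))
  repeat {
    d2 <- sqdist_to_centers(x, centers)
    new_assign <- max.col(-d2, ties.method = "first")
    # empty-cluster repair: move in the point farthest from its centroid
    repeat {
      sizes <- tabulate(new_assign, K)
      empty <- which(sizes == 0)
      if (length(empty) == 0) break
      cur <- d2[cbind(seq_len(nrow(x)), new_assign)]
      donor_ok <- sizes[new_assign] > 1
      far <- which.max(ifelse(donor_ok, cur, -Inf))
      new_assign[far] <- empty[1]
      centers[empty[1], ] <- x[far, ]
      d2[, empty[1]] <- sqdist_to_centers(x, centers[empty[1], , drop = FALSE])[, 1]
    }
    wcss <- sum(clamp0(d2[cbind(seq_len(nrow(x)), new_assign)]))
    wcss_trace <- c(wcss_trace, wcss)
    if (identical(new_assign, assign)) break
    assign <- new_assign
    centers <- rowsum(x, assign) / tabulate(assign, K)
    if (length(wcss_trace) > 200) break
  }
  list(assign = assign, centers = centers, wcss = wcss_trace[length(wcss_trace)],
       wcss_trace = wcss_trace)
}

#' Fit k-means by Lloyd's algorithm with k-means++ restarts
#'
#' Minimizes the within-cluster sum of squares (WCSS). Runs `n_init`
#' k-means++ seeded Lloyd descents (fixed seed) and keeps the best; empty
#' clusters are repaired by reassigning the point farthest from its
#' current centroid. Cluster labels are canonicalized by ascending
#' centroid Euclidean norm so signatures do not depend on the internal
#' label permutation.
#'
#' @param pool numeric matrix of pooled feature vectors.
#' @param K number of clusters, at most the number of distinct rows.
#' @param seed integer seed.
#' @param n_init number of restarts (default 10).
#' @return a `cluster_model`: centroids (canonical order), `K`, `wcss`,
#'   `wcss_trace` of the winning run, `assign` (canonical labels of the
#'   pooled rows) and the seed.
#' @export
kmeans_fit <- function(pool, K, seed = 1L, n_init = 10L) {
  pool <- as.matrix(pool)
  ndistinct <- nrow(unique(pool))
  if (K > ndistinct)
    stop_fccr("fccr_precondition_error",
              "K = %d exceeds the %d distinct pooled vectors", K, ndistinct)
  if (K < 1) stop_fccr("fccr_precondition_error", "K must be >= 1")
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_init)) {
      init <- kmeanspp_init(pool, K)
      fit <- lloyd_once(pool, init)
      if (is.null(best) || fit$wcss < best$wcss) best <- fit
    }
  })
  ord <- order(row_norms(best$centers), seq_len(K))   # ascending norm, stable
  canon <- integer(K); canon[ord] <- seq_len(K)       # raw label -> canonical
  structure(list(K = K, centroids = best$centers[ord, , drop = FALSE],
                 canonical_order = canon,
                 assign = canon[best$assign],
                 wcss = best$wcss, wcss_trace = best$wcss_trace,
                 seed = seed),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> K = %d, WCSS = %.4g (%d Lloyd iterations)\n",
              x$K, x$wcss, length(x$wcss_trace)))
  invisible(x)
}

#' Within-cluster sum of squares, centroid and pairwise forms
#'
#' The centroid form sums squared distances to cluster means; the pairwise
#' form sums, per cluster, half the mean pairwise squared distance. The
#' two are algebraically identical on any partition, which
#' `wcss_pairwise()` lets tests verify.
#'
#' @param pool pooled vectors.
#' @param assign integer cluster labels.
#' @return total WCSS.
#' @export
wcss_centroid <- function(pool, assign) {
  s <- 0
  for (k in unique(assign)) {
    xk <- pool[assign == k, , drop = FALSE]
    mu <- colMeans(xk)
    s <- s + sum(sweep(xk, 2, mu)^2)
  }
  s
}

#' @rdname wcss_centroid
#' @export
wcss_pairwise <- function(pool, assign) {
  s <- 0
  for (k in unique(assign)) {
    xk <- pool[assign == k, , drop = FALSE]
    nk <- nrow(xk)
    d2 <- as.matrix(stats::dist(xk))^2
    s <- s + sum(d2) / (2 * nk)
  }
  s
}

#' Replace feature vectors by cluster signatures
#'
#' Maps each (trial, channel) feature vector of the requested trials to
#' the canonical label of its nearest centroid (Euclidean; ties broken
#' toward the smaller canonical label), producing the compressed integer
#' matrix `X~` whose rows are trials and columns channels.
#'
#' @param model a `cluster_model`.
#' @param ft a `feature_tensor` with matching feature dimension.
#' @param idx trial indices to compress (default: all).
#' @return a `compressed_matrix`: integer matrix `length(idx) x C` (class
#'   attribute carries `K` and the source method).
#' @export
assign_signatures <- function(model, ft, idx = NULL) {
  dm <- dim(ft$values)
  if (dm[3] != ncol(model$centroids))
    stop_fccr("fccr_shape_error", "feature dimension %d != centroid dimension %d",
              dm[3], ncol(model$centroids))
  if (is.null(idx)) idx <- seq_len(dm[1])
  X <- matrix(NA_integer_, length(idx), dm[2])
  for (r in seq_along(idx)) {
    m <- array(ft$values[idx[r], , , drop = FALSE], c(dm[2], dm[3]))
    d2 <- sqdist_to_centers(m, model$centroids)
    X[r, ] <- max.col(-d2, ties.method = "first")  # centroids already canonical
  }
  structure(X, K = model$K, method = ft$method, class = "compressed_matrix")
}

#' @export
print.compressed_matrix <- function(x, ...) {
  cat(sprintf("<compressed_matrix> %d trials x %d channels, signatures 1..%d\n",
              nrow(x), ncol(x), attr(x, "K")))
  invisible(x)
}

#' Grid search over the number of clusters
#'
#' Evaluates each candidate `K` by running the downstream compression,
#' channel-ranking and LDA stages under an inner stratified
#' cross-validation on the training trials only, and selects the `K` with
#' the highest mean inner accuracy (ties toward the smaller `K`). The
#' default grid is the benchmark one: 2-8 step 2, 10-90 step 10, 100-700
#' step 200, intersected with feasibility (`K <= N_bar` and `K` at most
#' the number of distinct pooled vectors).
#'
#' @param ft a `feature_tensor` of the training trials' features.
#' @param labels class labels of those trials.
#' @param grid candidate cluster counts.
#' @param ranker,n_select,inner_folds downstream configuration: ranking
#'   algorithm, number of channels classified, inner fold count.
#' @param seed integer seed.
#' @return list with `K` (selected) and `table` (data.frame of K, mean
#'   inner accuracy, feasibility).
#' @export
grid_search_k <- function(ft, labels, grid = default_k_grid(),
                          ranker = "RFS", n_select = NULL,
                          inner_folds = 5L, seed = 1L) {
  dm <- dim(ft$values)
  nbar <- dm[1]
  ndistinct <- nrow(unique(matrix(ft$values, nbar * dm[2], dm[3])))
  feasible <- grid[grid <= nbar & grid <= ndistinct & grid >= 1]
  if (length(feasible) < length(grid))
    warning(sprintf("dropping infeasible K values: %s",
                    paste(setdiff(grid, feasible), collapse = ", ")))
  if (length(feasible) == 0)
    stop_fccr("fccr_precondition_error", "no feasible K in grid")
  if (is.null(n_select)) n_select <- dm[2]
  folds <- make_cv_folds(length(labels), labels, n_folds = inner_folds,
                         n_repeats = 1L, seed = seed)[[1]]
  acc <- vapply(feasible, function(K) {
    fold_acc <- vapply(seq_len(inner_folds), function(f) {
      tr <- which(folds != f); te <- which(folds == f)
      if (length(unique(labels[te])) < 2 || length(unique(labels[tr])) < 2)
        return(NA_real_)
      fit <- tryCatch(
        fit_fccr_stage(ft, labels, tr, K = K, ranker = ranker,
                       n_select = n_select, seed = seed),
        error = function(e) NULL)
      if (is.null(fit)) return(NA_real_)
      pred <- predict_fccr_stage(fit, ft, te)
      accuracy(labels[te], pred)
    }, 0)
    mean(fold_acc, na.rm = TRUE)
  }, 0)
  sel <- feasible[which.max(acc)]   # which.max -> first max -> smaller K
  list(K = sel,
       table = data.frame(K = feasible, inner_accuracy = acc))
}

#' The benchmark cluster-count grid
#' @return integer vector: 2-8 step 2, 10-90 step 10, 100-700 step 200.
#' @export
default_k_grid <- function() {
  c(seq(2L, 8L, 2L), seq(10L, 90L, 10L), seq(100L, 700L, 200L))
}
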