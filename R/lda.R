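#' Fit a regularized linear discriminant classifier
#'
#' Gaussian classes with a shared (pooled within-class) covariance:
#' class means, empirical priors, and the pooled covariance with a ridge
#' `lambda = ridge_scale * trace(S) / dim` added to the diagonal for
#' numerical stability with small folds.
#'
#' @param features numeric matrix, trials x features.
#' @param labels integer labels in `0..(L-1)`, at least 2 trials per class.
#' @param ridge_scale ridge multiplier (default 1e-6).
#' @return an `lda_model`.
#' @export
lda_fit <- function(features, labels, ridge_scale = 1e-6) {
  features <- as.matrix(features)
  if (!all(is.finite(features)))
    stop_fccr("fccr_numeric_error", "non-finite features")
  labels <- as.integer(labels)
  classes <- sort(unique(labels))
  counts <- table(factor(labels, levels = classes))
  if (any(counts < 2))
    stop_fccr("fccr_data_error", "every class needs at least 2 trials")
  n <- nrow(features); p <- ncol(features); L <- length(classes)
  means <- matrix(NA_real_, L, p)
  for (k in seq_along(classes))
    means[k, ] <- colMeans(features[labels == classes[k], , drop = FALSE])
  S <- matrix(0, p, p)
  for (k in seq_along(classes)) {
    xc <- sweep(features[labels == classes[k], , drop = FALSE], 2, means[k, ])
    S <- S + crossprod(xc)
  }
  S <- S / (n - L)
  lambda <- ridge_scale * sum(diag(S)) / p
  if (lambda <= 0) lambda <- ridge_scale
  S <- S + diag(lambda, p)
  Sinv <- solve(S)
  structure(list(classes = classes, means = means, priors = as.numeric(counts) / n,
                 cov = S, cov_inv = Sinv, lambda = lambda, p = p),
            class = "lda_model")
}

#' Predict class labels with a fitted LDA model
#'
#' Argmax of the linear discriminants
#' `x' S^{-1} mu_c - mu_c' S^{-1} mu_c / 2 + log pi_c`; exact ties go to
#' the smaller class label. Deterministic.
#'
#' @param model an `lda_model`.
#' @param features matrix with the model's feature dimension.
#' @return integer label vector.
#' @export
lda_predict <- function(model, features) {
  features <- as.matrix(features)
  if (ncol(features) != model$p)
    stop_fccr("fccr_shape_error", "feature dimension %d != model dimension %d",
              ncol(features), model$p)
  A <- model$cov_inv %*% t(model$means)                # p x L
  const <- -0.5 * colSums(t(model$means) * A) + log(model$priors)
  scores <- features %*% A + rep(const, each = nrow(features))
  model$classes[max.col(scores, ties.method = "first")]
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model> %d classes, %d features, ridge %.3g\n",
              length(x$classes), x$p, x$lambda))
  invisible(x)
}

#' Classification accuracy in percent
#'
#' `100 * mean(y == y_hat)`.
#'
#' @param y true labels.
#' @param y_hat predicted labels.
#' @return percent in `[0, 100]`.
#' @export
accuracy <- function(y, y_hat) {
  if (length(y) != length(y_hat) || length(y) < 1)
    stop_fccr("fccr_shape_error", "label vectors must have equal positive length")
  100 * mean(y == y_hat)
}

#' Precision, recall and F1 in percent
#'
#' Binary metrics with a designated positive class;
#' `F1 = 2 * precision * recall / (precision + recall)`. Zero
#' denominators yield 0 with a warning. The macro average over the two
#' one-vs-rest directions is also returned.
#'
#' @param y,y_hat binary label vectors.
#' @param positive_class the positive label (default 1).
#' @return named list: `precision`, `recall`, `f1` (percent), and
#'   `macro_precision`, `macro_recall`, `macro_f1`.
#' @export
precision_recall_f1 <- function(y, y_hat, positive_class = 1L) {
  if (length(y) != length(y_hat))
    stop_fccr("fccr_shape_error", "length mismatch")
  u <- unique(c(y, y_hat))
  if (length(u) > 2)
    stop_fccr("fccr_label_error", "binary labels required")
  one <- function(pos) {
    tp <- sum(y == pos & y_hat == pos)
    fp <- sum(y != pos & y_hat == pos)
    fn <- sum(y == pos & y_hat != pos)
    prec <- if (tp + fp == 0) {
      warning("no predicted positives; precision set to 0"); 0
    } else 100 * tp / (tp + fp)
    rec <- if (tp + fn == 0) {
      warning("no true positives in y; recall set to 0"); 0
    } else 100 * tp / (tp + fn)
    f1 <- if (prec + rec == 0) {
      warning("precision + recall = 0; F1 set to 0"); 0
    } else 2 * prec * rec / (prec + rec)
    c(prec, rec, f1)
  }
  m_pos <- one(positive_class)
  other <- setdiff(u, positive_class)
  m_neg <- if (length(other) == 1) suppressWarnings(one(other[1])) else m_pos
  list(precision = m_pos[1], recall = m_pos[2], f1 = m_pos[3],
       macro_precision = mean(c(m_pos[1], m_neg[1])),
       macro_recall = mean(c(m_pos[2], m_neg[2])),
       macro_f1 = mean(c(m_pos[3], m_neg[3])))
}
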