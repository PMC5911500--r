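#' One-hot class label indicator matrix
#'
#' @param labels integer labels in `0..(L-1)`.
#' @param L number of classes; every class must occur.
#' @return binary matrix `length(labels) x L` with exactly one 1 per row.
#' @export
make_label_indicator <- function(labels, L) {
  labels <- as.integer(labels)
  if (any(labels < 0) || any(labels >= L))
    stop_fccr("fccr_label_error", "labels outside 0..%d", L - 1)
  Y <- matrix(0, length(labels), L)
  Y[cbind(seq_along(labels), labels + 1L)] <- 1
  if (any(colSums(Y) < 1))
    stop_fccr("fccr_label_error", "every class must occur at least once")
  Y
}

# l2,1 norm: sum of row Euclidean norms
norm_l21 <- function(m) sum(row_norms(m))

#' Configuration for l2,1-robust channel ranking (RFS)
#'
#' @param alpha regularization weight (> 0, default 1).
#' @param max_iter maximum reweighting iterations.
#' @param rel_tol relative objective-change stopping tolerance.
#' @param row_norm_floor floor on row norms when forming the reweighting
#'   diagonal, guarding division by zero for exactly-zero rows.
#' @return an `rfs_config`.
#' @export
rfs_config <- function(alpha = 1, max_iter = 100L, rel_tol = 1e-6,
                       row_norm_floor = 1e-8) {
  if (alpha <= 0) stop_fccr("fccr_config_error", "alpha must be > 0")
  if (rel_tol <= 0 || row_norm_floor <= 0)
    stop_fccr("fccr_config_error", "tolerances must be positive")
  structure(list(alpha = alpha, max_iter = as.integer(max_iter),
                 rel_tol = rel_tol, row_norm_floor = row_norm_floor),
            class = "rfs_config")
}

rfs_objective <- function(X, Y, W, alpha) {
  norm_l21(X %*% W - Y) + alpha * norm_l21(W)
}

#' Channel ranking by l2,1-norm robust feature selection (RFS)
#'
#' Minimizes `J(W) = ||XW - Y||_{2,1} + alpha ||W||_{2,1}` by iterative
#' reweighting: with `A = [X, alpha*I]` and `U = [W; E]`, repeats
#' `U <- D^{-1} A' (A D^{-1} A')^{-1} Y` where `D` is diagonal with
#' `D_ii = 1 / (2 max(||U(i,:)||_2, floor))`, until the relative change of
#' `J` falls below `rel_tol`. `W` is the first `C` rows of `U`. Channels
#' are ranked by descending `||W(i,:)||_2`.
#'
#' @param X numeric matrix `N_bar x C` (compressed signatures used as
#'   reals, or any real design).
#' @param Y label indicator from [make_label_indicator()].
#' @param cfg an [rfs_config()].
#' @return a `channel_weights` object (see [rank_channels()]).
#' @export
rfs_rank <- function(X, Y, cfg = rfs_config()) {
  X <- unclass_matrix(X)
  if (!all(is.finite(X)) || !all(is.finite(Y)))
    stop_fccr("fccr_numeric_error", "non-finite entries in inputs")
  n <- nrow(X); C <- ncol(X); L <- ncol(Y)
  if (n < 2) stop_fccr("fccr_precondition_error", "need at least 2 rows")
  A <- cbind(X, diag(cfg$alpha, n))
  dinv <- rep(1, C + n)                     # D0 = I  =>  D^{-1} = I
  trace <- numeric(0)
  W <- matrix(0, C, L)
  J_prev <- Inf
  for (it in seq_len(cfg$max_iter)) {
    ADA <- A %*% (dinv * t(A))              # A D^-1 A'
    sol <- tryCatch(solve(ADA, Y), error = function(e) NULL)
    if (is.null(sol)) {
      ADA <- ADA + diag(1e-10 * sum(diag(ADA)) / n, n)
      sol <- tryCatch(solve(ADA, Y), error = function(e)
        stop_fccr("fccr_conditioning_error", "reweighted system is singular"))
    }
    U <- dinv * (t(A) %*% sol)
    rn <- pmax(row_norms(U), cfg$row_norm_floor)
    dinv <- 2 * rn                          # D^{-1}, D_ii = 1/(2 rn)
    W <- U[seq_len(C), , drop = FALSE]
    J <- rfs_objective(X, Y, W, cfg$alpha)
    trace <- c(trace, J)
    if (is.finite(J_prev) && abs(J_prev - J) <= cfg$rel_tol * max(J_prev, 1e-12))
      break
    J_prev <- J
  }
  channel_weights(W, algorithm = "RFS", objective_trace = trace)
}

#' Configuration for forward-backward greedy sparse regression (SSLSR)
#'
#' @param n_select target number of selected channels `C_bar`.
#' @param nu backward-elimination threshold in (0, 1); a channel is
#'   dropped only when the loss increase of removing it is below `nu`
#'   times the loss decrease of the preceding forward step.
#' @param max_iter maximum forward iterations `MI`.
#' @param epsilon stop when a forward step improves the loss by no more
#'   than this.
#' @param stop_at_ntrials if `TRUE`, reproduces the printed stopping rule
#'   that grows the selection to the number of trials instead of
#'   `n_select` (retained for comparison; the default treats that as a
#'   misprint since the row-support constraint caps the selection at
#'   `C_bar`).
#' @return an `sslsr_config`.
#' @export
sslsr_config <- function(n_select, nu = 0.5, max_iter = 100L, epsilon = 1e-10,
                         stop_at_ntrials = FALSE) {
  if (!(nu > 0 && nu < 1)) stop_fccr("fccr_config_error", "nu must be in (0,1)")
  if (max_iter < 1) stop_fccr("fccr_config_error", "max_iter must be >= 1")
  if (epsilon < 0) stop_fccr("fccr_config_error", "epsilon must be >= 0")
  structure(list(n_select = as.integer(n_select), nu = nu,
                 max_iter = as.integer(max_iter), epsilon = epsilon,
                 stop_at_ntrials = stop_at_ntrials),
            class = "sslsr_config")
}

sslsr_loss <- function(X, Y, W) sum((X %*% W - Y)^2) / nrow(X)

#' Channel ranking by structural sparse least-squares regression (SSLSR)
#'
#' Greedy forward-backward minimization of `L(W) = ||XW - Y||_F^2 / N`
#' under the row-support constraint `||W||_{2,0} <= C_bar`. Each forward
#' step adds the channel whose closed-form optimal weight row
#' `theta = (Y - XW)' X(:,i) / ||X(:,i)||^2` reduces the loss most (ties
#' toward the smaller channel index); a backward step then removes the
#' least-contributing selected channel if the loss increase is below `nu`
#' times the preceding decrease. Unselected channels keep zero rows and
#' rank below all selected ones.
#'
#' @param X numeric matrix `N_bar x C`; zero-variance (all-zero) columns
#'   are pre-screened out of the candidate set with a warning.
#' @param Y label indicator.
#' @param cfg an [sslsr_config()].
#' @return a `channel_weights` object; `$selected` holds the final
#'   selection in pick order, `$trajectory` the full forward/backward log.
#' @export
sslsr_rank <- function(X, Y, cfg) {
  X <- unclass_matrix(X)
  n <- nrow(X); C <- ncol(X); L <- ncol(Y)
  if (cfg$n_select > C)
    stop_fccr("fccr_config_error", "n_select = %d > C = %d", cfg$n_select, C)
  colsq <- colSums(X^2)
  candidates <- which(colsq > 0)
  if (length(candidates) < C)
    warning(sprintf("%d zero columns excluded from selection",
                    C - length(candidates)))
  if (sum(Y^2) == 0)
    stop_fccr("fccr_degenerate_target_error", "label indicator is all zero")
  W <- matrix(0, C, L)
  Fset <- integer(0)
  target_size <- if (cfg$stop_at_ntrials) min(n, length(candidates)) else cfg$n_select
  trajectory <- list()
  loss <- sslsr_loss(X, Y, W)
  iter <- 0L
  while (length(Fset) < target_size && iter < cfg$max_iter) {
    # forward: closed-form theta per unselected channel, pick best loss
    R <- Y - X %*% W
    best <- NULL
    for (i in setdiff(candidates, Fset)) {
      theta <- crossprod(R, X[, i]) / colsq[i]        # L x 1
      Wi <- W; Wi[i, ] <- Wi[i, ] + as.numeric(theta)
      l <- sslsr_loss(X, Y, Wi)
      if (is.null(best) || l < best$loss) best <- list(i = i, theta = theta, loss = l)
    }
    if (is.null(best)) break
    Fset <- c(Fset, best$i)
    W[best$i, ] <- W[best$i, ] + as.numeric(best$theta)
    delta_minus <- loss - best$loss
    trajectory[[length(trajectory) + 1]] <-
      list(step = "forward", channel = best$i, loss = best$loss,
           delta_minus = delta_minus)
    loss <- best$loss
    if (delta_minus <= cfg$epsilon) break
    iter <- iter + 1L
    # backward: least-contributing selected channel
    if (length(Fset) > 1) {
      rm_loss <- vapply(Fset, function(j) {
        Wj <- W; Wj[j, ] <- 0
        sslsr_loss(X, Y, Wj)
      }, 0)
      jmin <- Fset[which.min(rm_loss)]
      delta_plus <- min(rm_loss) - loss
      if (delta_plus < cfg$nu * delta_minus) {
        W[jmin, ] <- 0
        Fset <- setdiff(Fset, jmin)
        loss <- min(rm_loss)
        iter <- iter - 1L
        trajectory[[length(trajectory) + 1]] <-
          list(step = "backward", channel = jmin, loss = loss,
               delta_plus = delta_plus)
      }
    }
  }
  res <- channel_weights(W, algorithm = "SSLSR",
                         objective_trace = vapply(trajectory, `[[`, 0, "loss"),
                         selected = Fset)
  res$trajectory <- trajectory
  res
}

#' Channel weight result and ranking
#'
#' `channel_weights()` wraps a fitted `C x L` weight matrix; per-channel
#' weights are the row Euclidean norms and the ranking orders channels by
#' descending weight (ties toward the smaller channel index). For
#' selection-set algorithms, unselected channels have zero rows and thus
#' rank below every selected channel, in index order.
#'
#' @param W numeric matrix `C x L`.
#' @param algorithm character tag.
#' @param objective_trace per-iteration objective values.
#' @param selected optional selected-channel subset.
#' @return a `channel_weights` object with fields `W`, `weights`,
#'   `ranking`, `algorithm`, `objective_trace`, `selected`.
#' @export
channel_weights <- function(W, algorithm = "?", objective_trace = numeric(0),
                            selected = NULL) {
  if (!all(is.finite(W))) stop_fccr("fccr_numeric_error", "non-finite weights")
  w <- row_norms(W)
  structure(list(W = W, weights = w,
                 ranking = order(-w, seq_along(w)),
                 algorithm = algorithm,
                 objective_trace = objective_trace,
                 selected = selected),
            class = "channel_weights")
}

#' @rdname channel_weights
#' @param result a `channel_weights` object.
#' @export
rank_channels <- function(result) result$ranking

#' @export
print.channel_weights <- function(x, ...) {
  cat(sprintf("<channel_weights> %s: %d channels, top: %s\n",
              x$algorithm, length(x$weights),
              paste(utils::head(x$ranking, 5), collapse = " ")))
  invisible(x)
}

unclass_matrix <- function(X) {
  X <- unclass(X)
  attr(X, "K") <- NULL; attr(X, "method") <- NULL
  storage.mode(X) <- "double"
  X
}
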