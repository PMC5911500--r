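# Shared fixtures and independent oracles for the test suite.
# Everything is generated in code; no binary fixtures.

# small labelled trial set of pure noise
tiny_ts <- function(N = 6, M = 64, C = 3, fs = 100, seed = 1) {
  set.seed(seed)
  trial_set(array(rnorm(N * M * C), c(N, M, C)),
            labels = rep_len(c(0, 1), N), fs = fs)
}

# seeded random ranking instance: signatures-like integer design + labels
random_instance <- function(n, C, L = 2, K = 6, seed = 1) {
  set.seed(seed)
  X <- matrix(sample.int(K, n * C, replace = TRUE), n, C)
  labels <- rep_len(seq_len(L) - 1L, n)
  list(X = X + 0, Y = make_label_indicator(labels, L), labels = labels)
}

# ---- independent convex oracle for the RFS objective -----------------------
# generic quasi-Newton minimization of the delta-smoothed l2,1 objective;
# shares no code with the package's iteratively reweighted solver.
rfs_oracle_objective <- function(X, Y, alpha, delta = 1e-7, maxit = 5000) {
  C <- ncol(X); L <- ncol(Y)
  fn <- function(w) {
    W <- matrix(w, C, L); R <- X %*% W - Y
    sum(sqrt(rowSums(R^2) + delta^2)) + alpha * sum(sqrt(rowSums(W^2) + delta^2))
  }
  gr <- function(w) {
    W <- matrix(w, C, L); R <- X %*% W - Y
    S <- R / sqrt(rowSums(R^2) + delta^2)
    as.vector(t(X) %*% S + alpha * W / sqrt(rowSums(W^2) + delta^2))
  }
  W0 <- solve(crossprod(X) + diag(alpha, C), crossprod(X, Y))
  o <- stats::optim(as.vector(W0), fn, gr, method = "BFGS",
                    control = list(maxit = maxit, reltol = 1e-14))
  o$value
}

# ---- brute-force forward-backward greedy oracle ----------------------------
# direct reimplementation of the greedy selection from its verbal
# description: per-channel weights by least squares (lm.fit), explicit
# loops, no closed-form sharing with the package.
sslsr_oracle <- function(X, Y, n_select, nu = 0.5, max_iter = 100,
                         epsilon = 1e-10) {
  n <- nrow(X); C <- ncol(X)
  loss <- function(W) sum((X %*% W - Y)^2) / n
  W <- matrix(0, C, ncol(Y))
  Fset <- integer(0)
  log <- list()
  cur <- loss(W)
  iter <- 0
  while (length(Fset) < n_select && iter < max_iter) {
    cand <- setdiff(which(colSums(X^2) > 0), Fset)
    if (!length(cand)) break
    best_i <- NA; best_l <- Inf; best_W <- NULL
    for (i in cand) {
      # optimal single-channel weight row by an independent LS solve
      th <- stats::lm.fit(X[, i, drop = FALSE], Y - X %*% W)$coefficients
      Wi <- W; Wi[i, ] <- Wi[i, ] + as.numeric(th)
      li <- loss(Wi)
      if (li < best_l) { best_l <- li; best_i <- i; best_W <- Wi }
    }
    Fset <- c(Fset, best_i); W <- best_W
    dm <- cur - best_l
    log[[length(log) + 1]] <- list(step = "forward", channel = best_i)
    cur <- best_l
    if (dm <= epsilon) break
    iter <- iter + 1
    if (length(Fset) > 1) {
      rl <- sapply(Fset, function(j) { Wj <- W; Wj[j, ] <- 0; loss(Wj) })
      j <- Fset[which.min(rl)]
      if (min(rl) - cur < nu * dm) {
        W[j, ] <- 0; Fset <- setdiff(Fset, j); cur <- min(rl); iter <- iter - 1
        log[[length(log) + 1]] <- list(step = "backward", channel = j)
      }
    }
  }
  list(selected = Fset, trajectory = log, loss = cur, W = W)
}

# FFT periodogram band power with the same bin convention as the AR
# spectral features: bins [center - w/2, center + w/2), 0 Hz bin truncated
# at 0. Used as the spectral oracle.
periodogram_bins <- function(x, fs, centers = seq(0, 30, 3), width = 3) {
  n <- length(x)
  x <- x - mean(x)
  P <- Mod(stats::fft(x))^2 / n            # sum(P)/n = mean(x^2), two-sided
  freq <- (seq_len(n) - 1) * fs / n
  sapply(centers, function(cc) {
    lo <- max(0, cc - width / 2); hi <- cc + width / 2
    pos <- freq > 0 & freq >= lo & freq < hi & freq <= fs / 2
    dc <- if (lo <= 0) P[1] else 0
    (dc + 2 * sum(P[pos])) / n             # fold the mirrored half in
  })
}

# total band power of a signal in [lo, hi) Hz by periodogram
band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  x <- x - mean(x)
  P <- Mod(stats::fft(x))^2 / n^2
  freq <- (seq_len(n) - 1) * fs / n
  sum(P[freq >= lo & freq < hi & freq <= fs / 2]) * 2
}
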