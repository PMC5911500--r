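#' Configuration for robust unsupervised channel ranking (RUFS)
#'
#' Joint robust clustering and row-sparse regression: minimizes, over
#' nonnegative `G` (pseudo-label matrix, near-orthonormal columns),
#' `F` (cluster basis) and `W` (channel weights),
#' `||X - GF||_{2,1} + beta tr(G'LG) + gamma ||XW - G||_{2,1}
#'  + eta ||W||_{2,1}`, with `L` the normalized graph Laplacian of a
#' k-nearest-neighbour heat-kernel affinity on the trials.
#'
#' @param beta,gamma,eta non-negative regularization weights (default 1).
#' @param k_g neighbours in the affinity graph (default 5).
#' @param sigma_g heat-kernel bandwidth; `NULL` (default) uses the median
#'   pairwise distance.
#' @param delta smoothing constant for the l2,1 terms (default 1e-8): each
#'   term is computed as `sum_i sqrt(||row_i||^2 + delta^2)` so gradients
#'   exist at zero rows.
#' @param rho quadratic-penalty weight enforcing `G'G = I` (default 1e3).
#' @param max_outer maximum outer alternations (default 50).
#' @param rel_tol relative objective-change stopping tolerance.
#' @return a `rufs_config`.
#' @export
rufs_config <- function(beta = 1, gamma = 1, eta = 1, k_g = 5L,
                        sigma_g = NULL, delta = 1e-8, rho = 1e3,
                        max_outer = 50L, rel_tol = 1e-5) {
  if (any(c(beta, gamma, eta) < 0))
    stop_fccr("fccr_config_error", "beta, gamma, eta must be non-negative")
  structure(list(beta = beta, gamma = gamma, eta = eta, k_g = as.integer(k_g),
                 sigma_g = sigma_g, delta = delta, rho = rho,
                 max_outer = as.integer(max_outer), rel_tol = rel_tol),
            class = "rufs_config")
}

# smoothed l2,1: sum_i sqrt(||row_i||^2 + delta^2)
sl21 <- function(m, delta) sum(sqrt(rowSums(m * m) + delta^2))
# gradient factor: row_i / sqrt(||row_i||^2 + delta^2)
sl21_scale <- function(m, delta) m / sqrt(rowSums(m * m) + delta^2)

#' Normalized graph Laplacian of a kNN heat-kernel affinity
#'
#' @param X data matrix (rows are samples).
#' @param k_g neighbours per sample (mutual edges kept symmetric by union).
#' @param sigma_g bandwidth; `NULL` uses the median pairwise distance.
#' @return list with `laplacian` (symmetric PSD `n x n`) and `sigma`.
#' @export
knn_laplacian <- function(X, k_g = 5L, sigma_g = NULL) {
  n <- nrow(X)
  if (n <= k_g)
    stop_fccr("fccr_graph_error", "need more samples (%d) than neighbours (%d)",
              n, k_g)
  D <- as.matrix(stats::dist(X))
  if (is.null(sigma_g)) sigma_g <- stats::median(D[upper.tri(D)])
  if (sigma_g <= 0) sigma_g <- 1
  Wg <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[2:(k_g + 1)]
    Wg[i, nb] <- exp(-D[i, nb]^2 / (2 * sigma_g^2))
  }
  Wg <- pmax(Wg, t(Wg))               # symmetrize by union
  deg <- rowSums(Wg)
  if (any(deg == 0))
    stop_fccr("fccr_graph_error", "isolated sample in the affinity graph")
  s <- 1 / sqrt(deg)
  Lap <- diag(n) - (s * Wg) * rep(s, each = n)  # I - D^-1/2 W D^-1/2
  Lap <- (Lap + t(Lap)) / 2
  list(laplacian = Lap, sigma = sigma_g)
}

rufs_objective <- function(X, G, Fm, W, Lap, cfg) {
  sl21(X - G %*% Fm, cfg$delta) +
    cfg$beta * sum(diag(t(G) %*% Lap %*% G)) +
    cfg$gamma * sl21(X %*% W - G, cfg$delta) +
    cfg$eta * sl21(W, cfg$delta) +
    cfg$rho * sum((crossprod(G) - diag(ncol(G)))^2)
}

# projected-gradient descent with backtracking on fun/grad, projection >= 0;
# guaranteed not to increase the objective.
pg_descent <- function(par, fun, grad, steps = 5L, step0 = 1) {
  f0 <- fun(par)
  step <- step0
  for (s in seq_len(steps)) {
    g <- grad(par)
    ok <- FALSE
    for (bt in 1:30) {
      cand <- pmax(par - step * g, 0)
      fc <- fun(cand)
      if (fc <= f0) { ok <- TRUE; break }
      step <- step / 2
    }
    if (!ok) break
    if (fc < f0) step <- step * 1.5
    par <- cand
    if (f0 - fc <= 1e-12 * max(abs(f0), 1)) { f0 <- fc; break }
    f0 <- fc
  }
  par
}

#' Channel ranking by robust unsupervised feature selection (RUFS)
#'
#' Block-coordinate descent on the objective described in
#' [rufs_config()]: the trial affinity graph and its normalized Laplacian
#' are built once; `G` is initialized from seeded k-means on trials
#' (indicator columns scaled to orthonormality) and
#' `F <- [(G'G)^{-1} G' X]_+`; then the algorithm alternates a
#' bound-constrained quasi-Newton step on `W >= 0`, and projected-gradient
#' steps with backtracking on `G >= 0` (orthogonality `G'G = I` enforced
#' by the quadratic penalty) and on `F >= 0`. Each block step is accepted
#' only if it does not increase the (smoothed, penalized) objective, so
#' the recorded trace is non-increasing by construction.
#'
#' @param X numeric matrix `N_bar x C`.
#' @param cfg a [rufs_config()].
#' @param L pseudo-class count (default 2, the binary motor-imagery case).
#' @param seed integer seed for the k-means initialization.
#' @return a `channel_weights` object; `$G`, `$F`, `$laplacian_sigma` and
#'   `$objective_trace` (penalized objective per outer iteration) are
#'   attached.
#' @export
rufs_rank <- function(X, cfg = rufs_config(), L = 2L, seed = 1L) {
  X <- unclass_matrix(X)
  n <- nrow(X); C <- ncol(X)
  if (L > n) stop_fccr("fccr_precondition_error", "L must be <= N_bar")
  gr <- knn_laplacian(X, cfg$k_g, cfg$sigma_g)
  Lap <- gr$laplacian
  km <- kmeans_fit(X, K = L, seed = seed, n_init = 5L)
  G <- matrix(0, n, L)
  G[cbind(seq_len(n), km$assign)] <- 1
  G <- sweep(G, 2, sqrt(pmax(colSums(G), 1)), "/")    # G'G = I exactly
  Fm <- pmax(solve(crossprod(G) + diag(1e-10, L), t(G) %*% X), 0)
  W <- pmax(solve(crossprod(X) + diag(1, C), t(X) %*% G), 0)
  obj <- function() rufs_objective(X, G, Fm, W, Lap, cfg)
  trace <- obj()
  for (it in seq_len(cfg$max_outer)) {
    prev <- trace[length(trace)]
    # --- W step: L-BFGS-B over W >= 0 on the W-dependent terms
    wfun <- function(w) {
      Wm <- matrix(w, C, L)
      cfg$gamma * sl21(X %*% Wm - G, cfg$delta) + cfg$eta * sl21(Wm, cfg$delta)
    }
    wgrad <- function(w) {
      Wm <- matrix(w, C, L)
      S <- sl21_scale(X %*% Wm - G, cfg$delta)
      as.vector(cfg$gamma * t(X) %*% S + cfg$eta * sl21_scale(Wm, cfg$delta))
    }
    f_old <- wfun(as.vector(W))
    opt <- stats::optim(as.vector(W), wfun, wgrad, method = "L-BFGS-B",
                        lower = 0, control = list(maxit = 50))
    if (opt$value <= f_old) W <- matrix(opt$par, C, L)
    # --- G step: projected gradient on all G terms
    gfun <- function(g) {
      Gm <- matrix(g, n, L)
      sl21(X - Gm %*% Fm, cfg$delta) +
        cfg$beta * sum(diag(t(Gm) %*% Lap %*% Gm)) +
        cfg$gamma * sl21(X %*% W - Gm, cfg$delta) +
        cfg$rho * sum((crossprod(Gm) - diag(L))^2)
    }
    ggrad <- function(g) {
      Gm <- matrix(g, n, L)
      S1 <- sl21_scale(X - Gm %*% Fm, cfg$delta)
      S2 <- sl21_scale(X %*% W - Gm, cfg$delta)
      as.vector(-S1 %*% t(Fm) + 2 * cfg$beta * Lap %*% Gm - cfg$gamma * S2 +
                  4 * cfg$rho * Gm %*% (crossprod(Gm) - diag(L)))
    }
    G <- matrix(pg_descent(as.vector(G), gfun, ggrad, steps = 5L,
                           step0 = 1 / (1 + cfg$rho)), n, L)
    # --- F step: projected gradient on the reconstruction term
    ffun <- function(f) sl21(X - G %*% matrix(f, L, C), cfg$delta)
    fgrad <- function(f) {
      Fmm <- matrix(f, L, C)
      S <- sl21_scale(X - G %*% Fmm, cfg$delta)
      as.vector(-t(G) %*% S)
    }
    Fm <- matrix(pg_descent(as.vector(Fm), ffun, fgrad, steps = 5L), L, C)
    cur <- obj()
    if (!is.finite(cur))
      stop_fccr("fccr_numeric_error", "non-finite objective")
    trace <- c(trace, cur)
    if (abs(prev - cur) <= cfg$rel_tol * max(abs(prev), 1e-12)) break
  }
  res <- channel_weights(W, algorithm = "RUFS", objective_trace = trace)
  res$G <- G; res$F <- Fm; res$laplacian_sigma <- gr$sigma
  res$exact_objective <- sl21(X - G %*% Fm, 0) +
    cfg$beta * sum(diag(t(G) %*% Lap %*% G)) +
    cfg$gamma * sl21(X %*% W - G, 0) + cfg$eta * sl21(W, 0)
  res$orthogonality_gap <- sqrt(sum((crossprod(G) - diag(ncol(G)))^2))
  res
}
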