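#' Autoregressive spectral-power feature specification
#'
#' Band-integrated spectral power from a Burg-estimated AR model. The
#' defaults reproduce the standard BCI2000-style configuration: model
#' order 16, bin centers 0 to 30 Hz in 3 Hz steps (11 bins), 15 spectrum
#' evaluations per bin.
#'
#' @param model_order AR order `p` (default 16).
#' @param first_bin_hz,last_bin_hz,bin_width_hz bin-center grid in Hz.
#' @param evals_per_bin spectrum evaluations per bin (default 15).
#' @return an `ar_spec`.
#' @export
ar_spec <- function(model_order = 16, first_bin_hz = 0, last_bin_hz = 30,
                    bin_width_hz = 3, evals_per_bin = 15) {
  if (model_order < 1) stop_fccr("fccr_invariant_error", "model_order must be >= 1")
  nb <- (last_bin_hz - first_bin_hz) / bin_width_hz + 1
  if (abs(nb - round(nb)) > 1e-9 || nb < 1)
    stop_fccr("fccr_invariant_error", "bin grid must yield an integer bin count")
  if (evals_per_bin < 1)
    stop_fccr("fccr_invariant_error", "evals_per_bin must be >= 1")
  structure(list(model_order = as.integer(model_order),
                 first_bin_hz = first_bin_hz, last_bin_hz = last_bin_hz,
                 bin_width_hz = bin_width_hz,
                 evals_per_bin = as.integer(evals_per_bin),
                 n_bins = as.integer(round(nb))),
            class = "ar_spec")
}

#' Time-domain parameter feature specification
#'
#' Log variance of the signal and of its first and second forward
#' differences: amplitude, dominant high-frequency content, and change of
#' frequency respectively.
#'
#' @param derivative_orders distinct non-negative difference orders
#'   (default `c(0, 1, 2)`).
#' @param variance_floor positive floor applied to the variance before the
#'   logarithm, guarding `log(0)` for constant signals.
#' @return a `tdp_spec`.
#' @export
tdp_spec <- function(derivative_orders = c(0L, 1L, 2L), variance_floor = 1e-12) {
  derivative_orders <- as.integer(derivative_orders)
  if (any(derivative_orders < 0) || anyDuplicated(derivative_orders))
    stop_fccr("fccr_invariant_error", "orders must be distinct and non-negative")
  if (variance_floor <= 0)
    stop_fccr("fccr_invariant_error", "variance_floor must be positive")
  structure(list(derivative_orders = derivative_orders,
                 variance_floor = variance_floor),
            class = "tdp_spec")
}

#' Burg-method AR coefficients
#'
#' Fits an order-`p` autoregressive model by Burg's method and returns the
#' coefficients under the convention that the one-step prediction is
#' *minus* the weighted sum of past values,
#' `x_hat(t) = -sum_k a_p(k) x(t - k)`, i.e. the sign-flipped regression
#' coefficients. An AR(1) process generated with coefficient 0.9 therefore
#' yields `a_1` near -0.9.
#'
#' @param x numeric signal of length `M > 2p` with nonzero variance.
#' @param p model order.
#' @return numeric vector `a_p(1..p)`.
#' @export
fit_ar_coefficients <- function(x, p) {
  M <- length(x)
  if (M <= 2 * p)
    stop_fccr("fccr_insufficient_data_error", "need M > 2p (M = %d, p = %d)", M, p)
  if (stats::var(x) == 0)
    stop_fccr("fccr_degenerate_signal_error", "constant signal has no AR model")
  fit <- stats::ar.burg(x, aic = FALSE, order.max = p, demean = TRUE)
  -as.numeric(fit$ar)
}

# |H(f)|^2 of the all-pole AR filter with coefficients in the
# minus-sum convention: denominator 1 + sum_k a_k e^{-i 2 pi f k / fs}.
ar_psd_shape <- function(a, f_hz, fs) {
  k <- seq_along(a)
  E <- exp(-2i * pi * outer(f_hz / fs, k))      # |f| x p
  den <- Mod(1 + as.vector(E %*% a))^2
  1 / pmax(den, .Machine$double.xmin)
}

#' Band-integrated AR spectral power
#'
#' Evaluates the AR power spectrum on a fine grid, normalizes it to unit
#' integral over `[0, fs/2]`, scales by the signal's sample variance (the
#' total signal power), and integrates it over each frequency bin
#' `[center - w/2, center + w/2)` as the mean of `evals_per_bin` equally
#' spaced in-bin evaluations times the bin width. The 0 Hz bin evaluates
#' only non-negative frequencies and uses its effective (half) width.
#'
#' @param x numeric signal.
#' @param spec an [ar_spec()].
#' @param fs sampling rate, Hz; the top bin edge must stay below Nyquist.
#' @return numeric vector of `spec$n_bins` non-negative band powers.
#' @export
ar_spectral_power <- function(x, spec = ar_spec(), fs) {
  if (spec$last_bin_hz + spec$bin_width_hz / 2 >= fs / 2)
    stop_fccr("fccr_nyquist_error", "top bin edge must be below Nyquist")
  a <- fit_ar_coefficients(x, spec$model_order)
  # normalization grid over [0, fs/2]
  ngrid <- 512L
  fg <- seq(0, fs / 2, length.out = ngrid)
  sg <- ar_psd_shape(a, fg, fs)
  total <- sum((sg[-1] + sg[-ngrid]) / 2 * diff(fg))   # trapezoid
  scale <- stats::var(x) / total
  centers <- seq(spec$first_bin_hz, spec$last_bin_hz, by = spec$bin_width_hz)
  half <- spec$bin_width_hz / 2
  lo <- pmax(0, centers - half); hi <- centers + half
  # evals_per_bin points equally spaced inside each [lo, hi) (left-closed)
  off <- (seq_len(spec$evals_per_bin) - 1) / spec$evals_per_bin
  fe <- rep(lo, each = spec$evals_per_bin) +
    off * rep(hi - lo, each = spec$evals_per_bin)
  vals <- ar_psd_shape(a, fe, fs)
  binmean <- colMeans(matrix(vals, spec$evals_per_bin))
  binmean * (hi - lo) * scale
}

#' Time-domain parameters of a signal
#'
#' `TDP(p) = log(var(d^p x))` with the p-th derivative approximated by
#' p-fold forward first differences (sample-unit spacing; the constant
#' scale this drops is an additive offset after the log and is absorbed by
#' the downstream linear classifier). Variance uses denominator `n - 1`
#' and is floored at `spec$variance_floor` before the log.
#'
#' @param x numeric signal.
#' @param spec a [tdp_spec()].
#' @return numeric vector, one value per derivative order.
#' @export
tdp_features <- function(x, spec = tdp_spec()) {
  vapply(spec$derivative_orders, function(p) {
    d <- if (p == 0) x else diff(x, differences = p)
    if (length(d) < 2)
      stop_fccr("fccr_insufficient_data_error",
                "signal too short for derivative order %d", p)
    log(max(stats::var(d), spec$variance_floor))
  }, 0)
}

#' Per-channel feature extraction over a whole trial set
#'
#' Applies the spectral-power or time-domain extractor independently to
#' every (trial, channel) signal.
#'
#' @param ts a `trial_set`.
#' @param method `"SP"` (AR band powers, 11 values by default) or `"TDP"`
#'   (log-variance derivatives, 3 values).
#' @param spec an [ar_spec()] or [tdp_spec()]; a default is built when
#'   omitted.
#' @return a `feature_tensor`: list with `values` (array `N x C x d`),
#'   `method` and `d`.
#' @export
extract_features <- function(ts, method = c("SP", "TDP"), spec = NULL) {
  method <- match.arg(method)
  if (is.null(spec)) spec <- if (method == "SP") ar_spec() else tdp_spec()
  N <- n_trials(ts); C <- n_channels(ts)
  d <- if (method == "SP") spec$n_bins else length(spec$derivative_orders)
  vals <- array(NA_real_, c(N, C, d))
  for (i in seq_len(N)) {
    for (j in seq_len(C)) {
      x <- ts$trials[i, , j]
      f <- tryCatch(
        if (method == "SP") ar_spectral_power(x, spec, ts$fs)
        else tdp_features(x, spec),
        error = function(e) {
          stop_fccr("fccr_feature_error", "trial %d, channel %d: %s",
                    i, j, conditionMessage(e))
        })
      vals[i, j, ] <- f
    }
  }
  structure(list(values = vals, method = method, d = d, spec = spec,
                 channel_names = ts$channel_names),
            class = "feature_tensor")
}

#' @export
print.feature_tensor <- function(x, ...) {
  dm <- dim(x$values)
  cat(sprintf("<feature_tensor> %s: %d trials x %d channels x %d features\n",
              x$method, dm[1], dm[2], dm[3]))
  invisible(x)
}

#' Write / read a feature tensor as delimited text with a JSON sidecar
#'
#' The tensor is flattened to an `(N*C) x d` table (row order: channel
#' fastest) and written as TSV; the sidecar records the method, dimensions
#' and axis order so [read_feature_tensor()] can rebuild the array.
#'
#' @param ft a `feature_tensor`.
#' @param path output TSV path (`<path>.json` sidecar written next to it).
#' @return `path`, invisibly.
#' @export
write_feature_tensor <- function(ft, path) {
  dm <- dim(ft$values)
  flat <- matrix(aperm(ft$values, c(3, 2, 1)), ncol = dm[3], byrow = TRUE)
  utils::write.table(flat, path, sep = "\t", row.names = FALSE,
                     col.names = paste0("f", seq_len(dm[3])))
  jsonlite::write_json(list(method = ft$method, n_trials = dm[1],
                            n_channels = dm[2], d = dm[3],
                            axis_order = "trial,channel,feature",
                            channel_names = ft$channel_names),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_feature_tensor
#' @export
read_feature_tensor <- function(path) {
  man <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  flat <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE))
  vals <- aperm(array(t(flat), c(man$d, man$n_channels, man$n_trials)), c(3, 2, 1))
  structure(list(values = vals, method = man$method, d = man$d, spec = NULL,
                 channel_names = man$channel_names),
            class = "feature_tensor")
}
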