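#' FIR bandpass filter specification
#'
#' Window-method (Hamming) linear-phase FIR bandpass. The benchmark
#' configuration for 100 Hz motor-imagery recordings is a 0.1-40 Hz band
#' of order 33, which these defaults reproduce.
#'
#' @param low_hz lower passband edge, Hz (`0 <= low_hz < high_hz`).
#' @param high_hz upper passband edge, Hz (`< fs/2` of the data it is
#'   applied to).
#' @param order filter order (number of taps minus one), `>= 1`.
#' @return a `filter_spec`.
#' @export
filter_spec <- function(low_hz = 0.1, high_hz = 40, order = 33) {
  if (!(low_hz >= 0 && low_hz < high_hz))
    stop_fccr("fccr_invariant_error", "need 0 <= low_hz < high_hz")
  if (order < 1) stop_fccr("fccr_invariant_error", "order must be >= 1")
  structure(list(low_hz = low_hz, high_hz = high_hz, order = as.integer(order),
                 design = "window-method FIR"),
            class = "filter_spec")
}

#' Design the FIR taps for a filter specification
#'
#' Deterministic in (`spec`, `fs`): repeated designs are identical.
#'
#' @param spec a [filter_spec()].
#' @param fs sampling rate in Hz.
#' @return numeric vector of `order + 1` taps.
#' @export
fir_taps <- function(spec, fs) {
  if (spec$high_hz >= fs / 2)
    stop_fccr("fccr_nyquist_error",
              "high_hz = %g must be below Nyquist (%g Hz)", spec$high_hz, fs / 2)
  w <- c(spec$low_hz, spec$high_hz) / (fs / 2)
  as.numeric(signal::fir1(spec$order, w, type = "pass",
                          window = signal::hamming(spec$order + 1)))
}

#' Frequency response magnitude of FIR taps
#'
#' @param taps FIR coefficients.
#' @param f_hz frequencies to evaluate, Hz.
#' @param fs sampling rate, Hz.
#' @return numeric vector `|H(f)|`.
#' @export
fir_gain <- function(taps, f_hz, fs) {
  k <- seq_along(taps) - 1
  vapply(f_hz, function(f) Mod(sum(taps * exp(-2i * pi * f / fs * k))), 0)
}

#' Bandpass-filter every channel of every trial
#'
#' Applies the same linear-phase FIR taps to each (trial, channel) signal
#' in a single causal pass, then compensates the group delay by shifting
#' `floor(order/2)` samples, replicating the trailing edge so the output
#' keeps the input's shape.
#'
#' @param ts a `trial_set`.
#' @param spec a [filter_spec()].
#' @return a filtered `trial_set` of identical shape.
#' @export
bandpass_filter <- function(ts, spec = filter_spec()) {
  taps <- fir_taps(spec, ts$fs)
  shift <- spec$order %/% 2
  d <- dim(ts$trials)
  out <- ts$trials
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[3])) {
      x <- ts$trials[i, , j]
      # pad with replicated last value so the delayed output covers M samples
      xp <- c(x, rep(x[d[2]], shift))
      y <- as.numeric(stats::filter(xp, taps, method = "convolution",
                                    sides = 1))
      # causal convolution leaves the first length(taps)-1 outputs undefined;
      # seed them by replicating the leading edge before shifting
      y[seq_len(length(taps) - 1)][is.na(y[seq_len(length(taps) - 1)])] <-
        y[length(taps)]
      out[i, , j] <- y[(shift + 1):(shift + d[2])]
    }
  }
  ts$trials <- out
  ts
}

#' Analysis-window specification
#'
#' @param t_start window start in seconds relative to the cue.
#' @param t_end window end in seconds; must exceed `t_start`.
#' @return a `window_spec`.
#' @export
window_spec <- function(t_start, t_end) {
  if (!(t_start < t_end))
    stop_fccr("fccr_bounds_error", "need t_start < t_end (got [%g, %g])",
              t_start, t_end)
  structure(list(t_start = t_start, t_end = t_end), class = "window_spec")
}

#' Restrict trials to an analysis window
#'
#' Sample indices follow `index = round(t * fs)` with the half-open
#' convention `[start, end)`, so a `[0.5, 3.0]` s window at 100 Hz yields
#' exactly 250 samples.
#'
#' @param ts a `trial_set`.
#' @param w a [window_spec()].
#' @return a `trial_set` restricted in time; labels unchanged.
#' @export
extract_window <- function(ts, w) {
  M <- n_samples(ts)
  i0 <- round(w$t_start * ts$fs)
  i1 <- round(w$t_end * ts$fs)
  if (!(i0 >= 0 && i0 < i1 && i1 <= M))
    stop_fccr("fccr_bounds_error",
              "window [%g, %g] s maps to samples [%d, %d) outside 0..%d",
              w$t_start, w$t_end, i0, i1, M)
  if (i1 - i0 < 2)
    stop_fccr("fccr_invariant_error", "window shorter than 2 samples")
  ts$trials <- ts$trials[, (i0 + 1):i1, , drop = FALSE]
  ts
}
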