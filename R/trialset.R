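#' Epoched multichannel EEG trials
#'
#' Bundles an `N x M x C` array of epoched EEG (trial x time-sample x
#' channel, arbitrary microvolt-scale units) with integer class labels,
#' the sampling rate and channel names. All downstream stages of the
#' pipeline consume this container.
#'
#' @param trials numeric array `N x M x C`.
#' @param labels integer vector of length `N` with values in `0..(L-1)`;
#'   every class in that range must occur at least once.
#' @param fs sampling rate in Hz (positive).
#' @param channel_names character vector of length `C`, no duplicates.
#'   Defaults to `"ch1".."chC"`.
#' @param meta named list of free-form provenance.
#' @return an object of class `trial_set`.
#' @examples
#' x <- array(rnorm(2 * 10 * 3), c(2, 10, 3))
#' ts <- trial_set(x, labels = c(0, 1), fs = 100)
#' ts
#' @export
trial_set <- function(trials, labels, fs, channel_names = NULL, meta = list()) {
  if (!is.array(trials) || length(dim(trials)) != 3)
    stop_fccr("fccr_shape_error", "`trials` must be a 3-d array (trial x time x channel)")
  storage.mode(trials) <- "double"
  d <- dim(trials)
  if (d[1] < 1 || d[2] < 2 || d[3] < 1)
    stop_fccr("fccr_invariant_error", "need N >= 1, M >= 2, C >= 1; got %d x %d x %d",
              d[1], d[2], d[3])
  if (anyNA(trials) || any(!is.finite(trials)))
    stop_fccr("fccr_numeric_error", "`trials` contains non-finite values")
  labels <- as.integer(labels)
  if (length(labels) != d[1])
    stop_fccr("fccr_label_error", "length(labels) = %d but N = %d", length(labels), d[1])
  if (anyNA(labels) || any(labels < 0))
    stop_fccr("fccr_label_error", "labels must be non-negative integers")
  L <- max(labels) + 1L
  present <- sort(unique(labels))
  if (!identical(present, seq_len(L) - 1L))
    stop_fccr("fccr_label_error",
              "labels must cover every class in 0..%d; observed {%s}",
              L - 1L, paste(present, collapse = ","))
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop_fccr("fccr_invariant_error", "`fs` must be a positive scalar")
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(d[3]))
  channel_names <- as.character(channel_names)
  if (length(channel_names) != d[3])
    stop_fccr("fccr_shape_error", "channel_names length %d != C = %d",
              length(channel_names), d[3])
  if (anyDuplicated(channel_names))
    stop_fccr("fccr_invariant_error", "duplicate channel names")
  structure(
    list(trials = trials, labels = labels, fs = as.numeric(fs),
         channel_names = channel_names, n_classes = L, meta = meta),
    class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  d <- dim(x$trials)
  cat(sprintf("<trial_set> %d trials x %d samples x %d channels @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  tab <- table(x$labels)
  cat("  classes:", paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.trial_set <- function(object, ...) {
  d <- dim(object$trials)
  cat(sprintf("Epoched EEG: N = %d, M = %d (%.3g s), C = %d, fs = %g Hz\n",
              d[1], d[2], d[2] / object$fs, d[3], object$fs))
  cat("Channels:", paste(utils::head(object$channel_names, 8), collapse = ", "),
      if (d[3] > 8) "...", "\n")
  cat("Label counts:\n")
  print(table(label = object$labels))
  invisible(object)
}

#' Number of trials/samples/channels of a trial set
#' @param ts a `trial_set`.
#' @return integer.
#' @export
n_trials <- function(ts) dim(ts$trials)[1]

#' @rdname n_trials
#' @export
n_samples <- function(ts) dim(ts$trials)[2]

#' @rdname n_trials
#' @export
n_channels <- function(ts) dim(ts$trials)[3]

#' Subset trials of a trial set
#'
#' Keeps only the requested trials. Unlike the constructor this does not
#' require every class to remain present (cross-validation folds use it),
#' so it bypasses the class-coverage invariant on purpose.
#' @param ts a `trial_set`.
#' @param idx trial indices.
#' @return a `trial_set` (same class labels coding, possibly fewer classes).
#' @export
subset_trials <- function(ts, idx) {
  idx <- as.integer(idx)
  if (length(idx) == 0 || any(idx < 1) || any(idx > n_trials(ts)))
    stop_fccr("fccr_bounds_error", "trial indices out of range")
  out <- ts
  out$trials <- ts$trials[idx, , , drop = FALSE]
  out$labels <- ts$labels[idx]
  out
}

#' Save an epoched trial set to disk
#'
#' Two formats are supported. `"container"` writes a raw little-endian
#' binary file of doubles in trial-major order plus a JSON manifest
#' (`<path>.json`) holding dimensions, sampling rate, labels and channel
#' names; the round trip through [load_trialset()] is bit-exact.
#' `"edf"` writes a 16-bit European Data Format file (one data record per
#' trial) with a JSON sidecar carrying the labels; EDF quantizes amplitudes
#' to 16 bits, so that round trip preserves metadata exactly and signals
#' only to quantization precision.
#'
#' @param ts a `trial_set`.
#' @param path output file path (the manifest/sidecar is written next to it).
#' @param format `"container"` or `"edf"`.
#' @return `path`, invisibly.
#' @export
save_trialset <- function(ts, path, format = c("container", "edf")) {
  format <- match.arg(format)
  if (!inherits(ts, "trial_set"))
    stop_fccr("fccr_invariant_error", "`ts` must be a trial_set")
  dir <- dirname(path)
  if (!dir.exists(dir))
    stop_fccr("fccr_io_error", "directory does not exist: %s", dir)
  if (format == "container") {
    d <- dim(ts$trials)
    # trial-major layout: all samples/channels of trial 1, then trial 2, ...
    flat <- as.vector(aperm(ts$trials, c(3, 2, 1)))
    con <- file(path, "wb")
    on.exit(close(con), add = TRUE)
    writeBin(flat, con, size = 8, endian = "little")
    manifest <- list(format = "fccr-container-v1",
                     n_trials = d[1], n_samples = d[2], n_channels = d[3],
                     fs = ts$fs, labels = ts$labels,
                     channel_names = ts$channel_names, meta = ts$meta)
    jsonlite::write_json(manifest, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    write_edf(ts, path)
    jsonlite::write_json(list(labels = ts$labels),
                         paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' Load an epoched trial set from disk
#'
#' Inverse of [save_trialset()]. For the container format the arrays are
#' recovered bit-exactly; labels and channel names come from the JSON
#' manifest. For EDF, signals are reconstructed from the 16-bit samples
#' and labels are read from the JSON sidecar.
#'
#' @param path file path written by [save_trialset()].
#' @param format `"container"` or `"edf"`.
#' @return a `trial_set`.
#' @export
load_trialset <- function(path, format = c("container", "edf")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop_fccr("fccr_io_error", "file not found: %s", path)
  mpath <- paste0(path, ".json")
  if (format == "container") {
    if (!file.exists(mpath))
      stop_fccr("fccr_format_error", "missing manifest: %s", mpath)
    man <- jsonlite::read_json(mpath, simplifyVector = TRUE)
    need <- c("n_trials", "n_samples", "n_channels", "fs", "labels", "channel_names")
    if (!all(need %in% names(man)))
      stop_fccr("fccr_format_error", "manifest lacks fields: %s",
                paste(setdiff(need, names(man)), collapse = ", "))
    n <- man$n_trials * man$n_samples * man$n_channels
    sz <- file.info(path)$size
    if (sz != 8 * n)
      stop_fccr("fccr_shape_error",
                "array file has %d bytes, manifest implies %d", sz, 8 * n)
    con <- file(path, "rb")
    on.exit(close(con), add = TRUE)
    flat <- readBin(con, "double", n = n, size = 8, endian = "little")
    arr <- aperm(array(flat, c(man$n_channels, man$n_samples, man$n_trials)),
                 c(3, 2, 1))
    trial_set(arr, labels = man$labels, fs = man$fs,
              channel_names = man$channel_names,
              meta = man$meta %||% list())
  } else {
    edf <- read_edf(path)
    labels <- if (file.exists(mpath)) {
      unlist(jsonlite::read_json(mpath, simplifyVector = TRUE)$labels)
    } else {
      stop_fccr("fccr_label_error", "EDF input needs a label sidecar: %s", mpath)
    }
    trial_set(edf$trials, labels = labels, fs = edf$fs,
              channel_names = edf$channel_names,
              meta = list(source = "edf"))
  }
}

# ---- minimal EDF (16-bit European Data Format) ------------------------------
# Layout per the EDF specification: a 256-byte fixed header, 256 bytes of
# per-signal header fields, then data records of little-endian int16 samples.
# One data record per trial keeps the epoch structure recoverable.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  sprintf("%-*s", width, x)
}

write_edf <- function(ts, path) {
  d <- dim(ts$trials)
  N <- d[1]; M <- d[2]; C <- d[3]
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  hdr <- paste0(
    edf_pad("0", 8),                               # version
    edf_pad("fccr export", 80),                    # patient id
    edf_pad("synthetic or epoched EEG", 80),       # recording id
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),# date, time
    edf_pad(256 + 256 * C, 8),                     # header bytes
    edf_pad("", 44),                               # reserved
    edf_pad(N, 8),                                 # n data records
    edf_pad(format(M / ts$fs, digits = 7), 8),     # record duration (s)
    edf_pad(C, 4))                                 # n signals
  writeChar(hdr, con, eos = NULL)
  phys_min <- numeric(C); phys_max <- numeric(C)
  for (j in seq_len(C)) {
    rng <- range(ts$trials[, , j])
    if (rng[1] == rng[2]) rng <- rng + c(-1, 1)
    phys_min[j] <- rng[1]; phys_max[j] <- rng[2]
  }
  fields <- list(
    vapply(ts$channel_names, edf_pad, "", width = 16),
    rep(edf_pad("EEG", 80), C),
    rep(edf_pad("uV", 8), C),
    vapply(format(phys_min, digits = 7), edf_pad, "", width = 8),
    vapply(format(phys_max, digits = 7), edf_pad, "", width = 8),
    rep(edf_pad(-32768, 8), C),
    rep(edf_pad(32767, 8), C),
    rep(edf_pad("", 80), C),
    rep(edf_pad(M, 8), C),
    rep(edf_pad("", 32), C))
  for (f in fields) writeChar(paste(f, collapse = ""), con, eos = NULL)
  dig_rng <- 32767 - (-32768)
  for (i in seq_len(N)) {
    for (j in seq_len(C)) {
      x <- ts$trials[i, , j]
      dig <- round((x - phys_min[j]) / (phys_max[j] - phys_min[j]) * dig_rng - 32768)
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                  # header bytes
  rd(44)
  N <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  C <- as.integer(rd(4))
  ch <- trimws(vapply(seq_len(C), function(i) rd(16), ""))
  rd(80 * C); rd(8 * C)
  phys_min <- as.numeric(vapply(seq_len(C), function(i) rd(8), ""))
  phys_max <- as.numeric(vapply(seq_len(C), function(i) rd(8), ""))
  dig_min <- as.numeric(vapply(seq_len(C), function(i) rd(8), ""))
  dig_max <- as.numeric(vapply(seq_len(C), function(i) rd(8), ""))
  rd(80 * C)
  ns <- as.integer(vapply(seq_len(C), function(i) rd(8), ""))
  rd(32 * C)
  if (length(unique(ns)) != 1)
    stop_fccr("fccr_format_error", "EDF signals with unequal record lengths")
  M <- ns[1]
  fs <- M / dur
  trials <- array(0, c(N, M, C))
  for (i in seq_len(N)) {
    for (j in seq_len(C)) {
      dig <- readBin(con, "integer", n = M, size = 2, endian = "little")
      trials[i, , j] <- phys_min[j] +
        (dig - dig_min[j]) / (dig_max[j] - dig_min[j]) * (phys_max[j] - phys_min[j])
    }
  }
  list(trials = trials, fs = fs, channel_names = ch)
}
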