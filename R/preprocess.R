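#' Phonocardiogram signal trace
#'
#' Lightweight container for a uniformly sampled heart-sound signal.
#'
#' @param samples Numeric vector of amplitudes.
#' @param fs Sampling rate in Hz (> 0).
#' @return An object of class `pcg_trace` with elements `samples` and `fs`.
#' @export
pcg_trace <- function(samples, fs) {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number")
  if (length(samples) < 1) stop("trace must contain at least one sample")
  if (any(!is.finite(samples))) stop("trace contains non-finite samples")
  structure(list(samples = samples, fs = fs), class = "pcg_trace")
}

#' @export
print.pcg_trace <- function(x, ...) {
  cat(sprintf("<pcg_trace> %d samples @ %g Hz (%.3f s)\n",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' Load a PCG recording from a WAV file
#'
#' Reads a mono or multi-channel WAV file (channels are averaged to mono,
#' matching single-channel stethoscope capture) and optionally resamples to
#' a target rate. The window constants of the segmentation stage are sample
#' counts tied to 44.1 kHz, so recordings at other rates are resampled to
#' 44.1 kHz by default; pass `fs_target = NA` to keep the native rate (all
#' window lengths then scale with `fs` as time constants).
#'
#' @param path Path to a readable WAV file.
#' @param fs_target Target sampling rate in Hz, or `NA` to disable resampling.
#' @return A [pcg_trace()].
#' @export
load_recording <- function(path, fs_target = 44100) {
  if (!file.exists(path)) stop("cannot read recording: ", path)
  w <- read_wav(path)
  x <- rowMeans(w$samples)
  fs <- w$fs
  if (!is.na(fs_target) && fs != fs_target) {
    r <- ratio_approx(fs_target / fs)
    x <- signal::resample(x, r$p, r$q)
    fs <- fs_target
  }
  pcg_trace(x, fs)
}

# small-denominator rational approximation of a resampling ratio
ratio_approx <- function(r, max_den = 1000L) {
  best <- c(p = round(r), q = 1)
  best_err <- abs(r - best["p"])
  for (q in seq_len(max_den)) {
    p <- round(r * q)
    err <- abs(r - p / q)
    if (err < best_err - 1e-15) {
      best <- c(p = p, q = q)
      best_err <- err
    }
    if (best_err < 1e-12) break
  }
  list(p = as.integer(best[["p"]]), q = as.integer(best[["q"]]))
}

#' Band-limit a heart-sound trace by wavelet decomposition
#'
#' Decomposes the trace with a db10 multilevel wavelet transform, zeroes the
#' approximation and every detail band whose nominal frequency range
#' `[fs/2^(j+1), fs/2^j]` falls outside `(low, high)`, and reconstructs.
#' Heart sounds carry their energy in roughly 20-700 Hz; the defaults retain
#' approximately 21.5-689 Hz at 44.1 kHz (detail levels 6-10 of a 10-level
#' decomposition).
#'
#' @param trace A [pcg_trace()].
#' @param low,high Passband edges in Hz.
#' @return A band-limited [pcg_trace()].
#' @export
bandlimit <- function(trace, low = 21.5, high = 689) {
  stopifnot(inherits(trace, "pcg_trace"))
  fs <- trace$fs
  if (fs < 2 * high) stop("sampling rate too low for requested band")
  # depth chosen so the residual approximation band is ~[0, low]
  levels <- max(1L, as.integer(round(log2(fs / (2 * low)))))
  dec <- dwt_multilevel(trace$samples, levels)
  dec$approx[] <- 0
  for (j in seq_len(dec$levels)) {
    band_lo <- fs / 2^(j + 1)
    band_hi <- fs / 2^j
    if (!(band_lo < high && band_hi > low)) dec$details[[j]][] <- 0
  }
  pcg_trace(idwt_multilevel(dec), fs)
}

#' Normalize a trace to unit peak amplitude
#'
#' @param trace A [pcg_trace()].
#' @return The trace divided by `max(abs(samples))`.
#' @export
normalize_trace <- function(trace) {
  stopifnot(inherits(trace, "pcg_trace"))
  peak <- max(abs(trace$samples))
  if (peak == 0) stop("cannot normalize an all-zero trace")
  pcg_trace(trace$samples / peak, trace$fs)
}

#' Preprocess a recording: band-limit then normalize
#'
#' @inheritParams bandlimit
#' @return A filtered, unit-peak [pcg_trace()].
#' @export
preprocess_trace <- function(trace, low = 21.5, high = 689) {
  normalize_trace(bandlimit(trace, low, high))
}
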