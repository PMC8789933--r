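#' Magnitude spectrum of a segment
#'
#' Magnitude of the length-M discrete Fourier transform of the segment,
#' restricted to the half spectrum (bins `0 .. floor(M/2)`); the magnitude
#' DFT of a real signal is symmetric, and the Hz-valued width/gravity
#' features are only meaningful on the half spectrum. No zero padding: the
#' bin resolution is the segment's own `fs / M`.
#'
#' @param segment A [pcg_trace()].
#' @return Object of class `pcg_spectrum`: `values` (nonnegative), `bin_hz`,
#'   `fs`.
#' @export
magnitude_spectrum <- function(segment) {
  stopifnot(inherits(segment, "pcg_trace"))
  x <- segment$samples
  M <- length(x)
  if (M < 2) stop("segment too short for a spectrum")
  v <- Mod(stats::fft(x))[seq_len(M %/% 2 + 1L)]
  structure(list(values = v, bin_hz = segment$fs / M, fs = segment$fs),
            class = "pcg_spectrum")
}

# combined secondary-envelope weight vector over offsets -(L1+L2)..(L1+L2):
# triangular outer weights minus an inner rectangular window (empty when
# L1 - L2 - 1 < 0, i.e. the printed L1 = 9, L2 = 17 setting)
secondary_weights <- function(L1, L2) {
  span <- L1 + L2
  l1 <- -span:span
  w <- L1 + L2 + 1 - abs(l1)
  r <- L1 - L2 - 1
  if (r >= 0) {
    inner <- abs(l1) <= r
    w[inner] <- w[inner] - 1
  }
  w / ((2 * L1 + 1) * (2 * L2 + 1))
}

#' Smoothed secondary envelope of a magnitude spectrum
#'
#' Applies the double-window smoothing operator (a triangular-weighted sum
#' over `|l| <= L1+L2` minus an inner rectangular sum, normalized by
#' `(2L1+1)(2L2+1)`) to the half spectrum, with reflected padding at the
#' edges, then clamps any negative values at zero and normalizes to unit
#' maximum. With the default `(L1, L2) = (9, 17)` the inner window range is
#' empty and the operator is a pure triangular smoother; `swap_windows`
#' exchanges the two roles.
#'
#' @param spectrum A `pcg_spectrum` from [magnitude_spectrum()].
#' @param L1,L2 Smoothing half-widths in bins.
#' @param swap_windows Exchange the roles of `L1` and `L2`.
#' @return Object of class `pcg_spec_envelope`: `values` (max 1), `bin_hz`.
#' @export
secondary_envelope <- function(spectrum, L1 = 9, L2 = 17, swap_windows = FALSE) {
  if (swap_windows) { tmp <- L1; L1 <- L2; L2 <- tmp }
  x <- spectrum$values
  n <- length(x)
  pad <- L1 + L2
  if (n <= 2 * pad + 1) stop("spectrum too short for the smoothing windows")
  w <- secondary_weights(L1, L2)
  xp <- c(rev(x[2:(pad + 1)]), x, rev(x[(n - pad):(n - 1)]))
  sm <- stats::filter(xp, w, method = "convolution", sides = 2)
  v <- as.numeric(sm[(pad + 1):(pad + n)])
  v[v < 0] <- 0
  peak <- max(v)
  if (peak == 0) stop("degenerate spectrum: envelope is identically zero")
  structure(list(values = v / peak, bin_hz = spectrum$bin_hz),
            class = "pcg_spec_envelope")
}

#' Spectral gravity center of an envelope
#'
#' Frequency-weighted mean `sum(k * env[k]) / sum(env[k])` over 0-based bins,
#' converted to Hz.
#'
#' @param env A `pcg_spec_envelope`.
#' @return Gravity center in Hz.
#' @export
gravity_center <- function(env) {
  v <- env$values
  s <- sum(v)
  if (s == 0) stop("cannot compute gravity of a zero envelope")
  k <- seq_along(v) - 1
  sum(k * v) / s * env$bin_hz
}

#' Threshold-crossing frequency widths of an envelope
#'
#' For each threshold `Thv`, the width is the span in Hz between the first
#' and last bins where the unit-normalized envelope exceeds `Thv` (outermost
#' crossings, integer bins). An envelope that never exceeds a threshold gets
#' width 0, so the feature vector stays total even for sounds with missing
#' spectral components.
#'
#' @param env A `pcg_spec_envelope` (unit maximum).
#' @param thv_list Thresholds in (0, 1).
#' @return Named numeric vector of widths in Hz, one per threshold.
#' @export
frequency_widths <- function(env, thv_list = c(0.3, 0.5, 0.8)) {
  if (any(thv_list <= 0 | thv_list >= 1)) stop("thresholds must lie in (0, 1)")
  v <- env$values
  out <- vapply(thv_list, function(thv) {
    idx <- which(v > thv)
    if (length(idx) == 0) 0 else (max(idx) - min(idx)) * env$bin_hz
  }, numeric(1))
  names(out) <- paste0("Thv", thv_list)
  out
}

#' Eight-dimensional frequency-feature vector of a cycle
#'
#' Composes, for each of CS1 and CS2, the three threshold-crossing widths
#' (default thresholds 0.3, 0.5, 0.8) and the spectral gravity center of its
#' secondary spectrum envelope, in the order
#' `CS1_FW1, CS1_FW2, CS1_FW3, CS1_G, CS2_FW1, CS2_FW2, CS2_FW3, CS2_G`
#' (all Hz).
#'
#' @param cs1,cs2 [pcg_trace()] segments of one cycle.
#' @param L1,L2,swap_windows Passed to [secondary_envelope()].
#' @param thv_list Passed to [frequency_widths()].
#' @return Named numeric vector of length 8.
#' @export
feature_vector <- function(cs1, cs2, L1 = 9, L2 = 17, swap_windows = FALSE,
                           thv_list = c(0.3, 0.5, 0.8)) {
  one <- function(seg) {
    env <- secondary_envelope(magnitude_spectrum(seg), L1, L2, swap_windows)
    c(frequency_widths(env, thv_list), G = gravity_center(env))
  }
  ff <- c(one(cs1), one(cs2))
  names(ff) <- ff_feature_names()
  ff
}

#' Canonical feature names of the 8-dimensional vector
#' @return Character vector of length 8.
#' @export
ff_feature_names <- function() {
  c("CS1_FW1", "CS1_FW2", "CS1_FW3", "CS1_G",
    "CS2_FW1", "CS2_FW2", "CS2_FW3", "CS2_G")
}

#' Feature matrix for a list of segmented cycles
#'
#' @param cycles List of cycles from [extract_cycles()] /
#'   [segment_recording()].
#' @param ... Passed to [feature_vector()].
#' @return Numeric matrix, one row per cycle, 8 named columns.
#' @export
cycles_features <- function(cycles, ...) {
  ff <- t(vapply(cycles, function(cy) feature_vector(cy$cs1, cy$cs2, ...),
                 numeric(8)))
  colnames(ff) <- ff_feature_names()
  ff
}
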