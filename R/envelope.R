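#' Viola-integral (windowed local-variance) envelope
#'
#' For each sample m in the valid range, the envelope is the variance of the
#' trace over the window `[m - half_width, m + half_width]` (population
#' variance, i.e. divided by the window length). The border outside the valid
#' range is filled by edge replication and the result is normalized to unit
#' maximum. The default half-width is 50 ms of signal (2205 samples at
#' 44.1 kHz).
#'
#' @param trace A [pcg_trace()].
#' @param half_width Window half-width in samples.
#' @return An object of class `pcg_envelope`: `values` (length-M, max 1),
#'   `fs`, `half_width`, `valid` (1-based index range of directly computed
#'   values).
#' @export
viola_envelope <- function(trace, half_width = round(0.05 * trace$fs)) {
  stopifnot(inherits(trace, "pcg_trace"))
  x <- trace$samples
  M <- length(x)
  W <- as.integer(half_width)
  if (W < 1) stop("half_width must be >= 1")
  if (M <= 2 * W) stop("trace shorter than the envelope window")
  width <- 2 * W + 1
  # windowed variance is invariant to a global shift; centering first
  # avoids catastrophic cancellation in the running-sum formulation
  x <- x - mean(x)
  cs1 <- cumsum(x)
  cs2 <- cumsum(x^2)
  # windowed sums for centers m = W..(M-1-W) (0-based)
  hi <- seq.int(width, M)
  s1 <- cs1[hi] - c(0, cs1[seq_len(M - width)])
  s2 <- cs2[hi] - c(0, cs2[seq_len(M - width)])
  v <- s2 / width - (s1 / width)^2
  v[v < 0] <- 0  # guard tiny negative round-off
  peak <- max(v)
  if (peak == 0) stop("zero-variance trace: envelope cannot be normalized")
  v <- v / peak
  values <- c(rep(v[1], W), v, rep(v[length(v)], W))
  structure(list(values = values, fs = trace$fs, half_width = W,
                 valid = c(W + 1L, M - W)),
            class = "pcg_envelope")
}

#' Antisymmetric STMHT kernel
#'
#' Length-N kernel of the short-time modified Hilbert transform; N must be
#' odd. The kernel is odd about its (zero-valued) center tap, so it sums to
#' zero and responds only to asymmetry of the envelope inside the window.
#'
#' @param N Odd window length in samples.
#' @return Numeric vector of length `N`.
#' @export
stmht_kernel <- function(N) {
  N <- as.integer(N)
  if (N < 3 || N %% 2 == 0) stop("window length N must be odd and >= 3")
  i <- seq.int(0, N - 1)
  a <- (N - 1 - 2 * i)
  k <- (cos(a * pi / (2 * N)) - cos(a * pi / 2)) / (N * sin(a * pi / (2 * N)))
  k[(N - 1) %/% 2 + 1] <- 0
  k
}

#' Short-time modified Hilbert transform of an envelope
#'
#' Slides the antisymmetric kernel of [stmht_kernel()] (under a rectangular
#' moving window) across the envelope. Output is defined for centers
#' `[(N-1)/2, M-1-(N-1)/2]` (0-based); the borders are zero. The default
#' window is about one second of signal (44101 samples at 44.1 kHz), i.e. on
#' the order of one cardiac cycle, which is what makes the signed zero
#' crossings land on burst centers and inter-burst midpoints.
#'
#' @param env A `pcg_envelope` (or any list with `values` and `fs`).
#' @param window_length Odd window length N in samples.
#' @return Object of class `pcg_stmht`: `values`, `fs`, `window_length`,
#'   `valid`.
#' @export
stmht <- function(env, window_length = 2 * floor(env$fs / 2) + 1) {
  x <- env$values
  M <- length(x)
  N <- as.integer(window_length)
  if (N %% 2 == 0) stop("window length N must be odd")
  if (M <= N) stop("envelope shorter than the STMHT window")
  k <- stmht_kernel(N)
  # cross-correlation of x with k via FFT convolution
  # (stats::convolve(x, y, type = "open") convolves x with the reverse of y,
  # which is exactly the sliding inner product of x and k)
  z <- stats::convolve(x, k, type = "open")
  half <- (N - 1L) %/% 2L
  values <- numeric(M)
  values[(half + 1L):(M - half)] <- z[N:M]
  structure(list(values = values, fs = env$fs, window_length = N,
                 valid = c(half + 1L, M - half)),
            class = "pcg_stmht")
}

#' Signed zero crossings of an STMHT trace
#'
#' Computes the signum sequence of the STMHT values (exact zeros carry the
#' neighbouring nonzero sign so a `-,0,+` run yields a single event), its
#' first difference, and reports negative-to-positive (N2P, difference +2)
#' and positive-to-negative (P2N, difference -2) crossing times in seconds.
#' The reported time is `i / fs` for the (0-based) sample index `i`
#' immediately before the crossing.
#'
#' Genuine burst-center and midpoint crossings are separated by a quarter
#' cycle or more, whereas noise makes the STMHT wobble across zero in
#' near-flat regions, producing pairs of opposite crossings milliseconds
#' apart. Adjacent crossing pairs closer than `min_event_gap` are therefore
#' removed (shortest pair first, repeatedly); the default 50 ms matches the
#' envelope window time constant. Set `min_event_gap = 0` for the raw
#' crossing set.
#'
#' @param st A `pcg_stmht` (or list with `values` and `fs`).
#' @param fs Sampling rate; defaults to `st$fs`.
#' @param min_event_gap Minimum separation (s) between retained crossings.
#' @return Object of class `pcg_events`: `n2p`, `p2n` (times in s,
#'   ascending), `signum`, `dsignum`.
#' @export
zero_cross_events <- function(st, fs = st$fs, min_event_gap = 0.05) {
  v <- st$values
  s <- sign(v)
  nz <- which(s != 0)
  if (length(nz) == 0) stop("no sign changes: STMHT trace is identically zero")
  # carry previous nonzero sign across zero dwells; leading zeros take the
  # first nonzero sign (no spurious event at the zero-padded border)
  filled <- s
  filled[seq_len(nz[1])] <- s[nz[1]]
  for (idx in which(filled == 0)) filled[idx] <- filled[idx - 1L]
  ds <- diff(filled)
  n2p_i <- which(ds == 2) - 1L   # 0-based index before the crossing
  p2n_i <- which(ds == -2) - 1L
  if (length(n2p_i) + length(p2n_i) == 0)
    stop("no sign changes found in STMHT trace")
  # drop blip pairs: adjacent opposite crossings closer than min_event_gap
  times <- c(n2p_i, p2n_i) / fs
  kind <- rep(c("N2P", "P2N"), c(length(n2p_i), length(p2n_i)))
  ord <- order(times)
  times <- times[ord]
  kind <- kind[ord]
  repeat {
    if (length(times) < 2) break
    gaps <- diff(times)
    j <- which.min(gaps)
    if (gaps[j] >= min_event_gap) break
    times <- times[-c(j, j + 1)]
    kind <- kind[-c(j, j + 1)]
  }
  n2p_t <- times[kind == "N2P"]
  p2n_t <- times[kind == "P2N"]
  structure(list(n2p = n2p_t, p2n = p2n_t,
                 signum = s, dsignum = ds, fs = fs),
            class = "pcg_events")
}
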