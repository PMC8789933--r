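#' Pair STMHT events into per-cycle CS1/CS2 boundaries
#'
#' N2P events sit on the centers of the S1/S2 bursts and P2N events on the
#' midpoints between bursts. Because diastole (S2 to next S1) is longer than
#' systole (S1 to S2), the difference sequence of consecutive N2P times
#' identifies which gap is which: if the gap after N2P i is the shorter one,
#' the cycle's CS2-to-CS1 boundary is P2N i and the CS1-to-CS2 split is the
#' following P2N; otherwise both shift one P2N later. Boundaries are then
#' chained into cycles `(cs21, cs12, cs21_next)`.
#'
#' The recurrence indexes the two streams with the P2N stream leading: the
#' i-th P2N is the inter-burst midpoint just before the i-th N2P. Leading
#' N2P events before the first P2N are therefore dropped (a boundary for
#' them is unobservable anyway). Duplicated or non-increasing boundary
#' candidates produced by the recurrence are deduplicated, and pairing stops
#' where the recurrence would index past either event array.
#'
#' @param ev A `pcg_events` object from [zero_cross_events()].
#' @return A data.frame with columns `cs21`, `cs12`, `cs21_next` (seconds),
#'   one row per complete cycle.
#' @export
pair_boundaries <- function(ev) {
  p2n <- ev$p2n
  if (length(p2n) == 0) stop("segmentation failure: no P2N events")
  n2p <- ev$n2p[ev$n2p > p2n[1]]   # align so each P2N[i] precedes N2P[i]
  if (length(n2p) < 3 || length(p2n) < 3)
    stop("segmentation failure: need at least 3 N2P and 3 P2N events")
  d <- diff(n2p)
  cs21 <- numeric(0)
  cs12 <- numeric(0)
  for (i in seq_len(length(d) - 1L)) {
    if (d[i] < d[i + 1]) {
      if (i + 1 > length(p2n)) break
      b21 <- p2n[i]; b12 <- p2n[i + 1]
    } else {
      if (i + 2 > length(p2n)) break
      b21 <- p2n[i + 1]; b12 <- p2n[i + 2]
    }
    if (length(cs21) > 0 && b21 <= cs12[length(cs12)]) next  # duplicate/overlap
    cs21 <- c(cs21, b21)
    cs12 <- c(cs12, b12)
  }
  if (length(cs21) < 2)
    stop("segmentation failure: could not form a complete cycle")
  data.frame(cs21 = cs21[-length(cs21)],
             cs12 = cs12[-length(cs12)],
             cs21_next = cs21[-1])
}

#' Slice a trace into per-cycle CS1/CS2 segments
#'
#' Segments are half-open sample spans: CS1 covers `[cs21, cs12)` and CS2
#' covers `[cs12, cs21_next)`, so adjacent segments never share a sample and
#' their concatenation reproduces the inter-boundary span exactly.
#'
#' @param trace A [pcg_trace()] (normally the preprocessed trace).
#' @param boundaries Data.frame from [pair_boundaries()].
#' @return List of cycles; each element has `cs1` and `cs2` ([pcg_trace()]s)
#'   and the boundary times `cs21`, `cs12`, `cs21_next`.
#' @export
extract_cycles <- function(trace, boundaries) {
  stopifnot(inherits(trace, "pcg_trace"))
  fs <- trace$fs
  M <- length(trace$samples)
  lapply(seq_len(nrow(boundaries)), function(i) {
    i21 <- round(boundaries$cs21[i] * fs)
    i12 <- round(boundaries$cs12[i] * fs)
    i21n <- round(boundaries$cs21_next[i] * fs)
    if (i21 < 0 || i21n > M) stop("cycle boundary outside trace")
    if (!(i21 < i12 && i12 < i21n)) stop("invalid cycle boundary ordering")
    list(cs1 = pcg_trace(trace$samples[(i21 + 1L):i12], fs),
         cs2 = pcg_trace(trace$samples[(i12 + 1L):i21n], fs),
         cs21 = boundaries$cs21[i], cs12 = boundaries$cs12[i],
         cs21_next = boundaries$cs21_next[i])
  })
}

#' Segment a preprocessed recording into CS1/CS2 cycles
#'
#' Convenience wrapper chaining [viola_envelope()], [stmht()],
#' [zero_cross_events()], [pair_boundaries()] and [extract_cycles()].
#'
#' @param trace A preprocessed [pcg_trace()].
#' @param half_width Envelope window half-width in samples (default 50 ms).
#' @param window_length STMHT window length in samples (default ~1 s, odd).
#' @return List with `cycles` (see [extract_cycles()]), `boundaries`,
#'   `events`, `envelope`, `stmht`.
#' @export
segment_recording <- function(trace,
                              half_width = round(0.05 * trace$fs),
                              window_length = 2 * floor(trace$fs / 2) + 1) {
  env <- viola_envelope(trace, half_width)
  st <- stmht(env, window_length)
  ev <- zero_cross_events(st)
  b <- pair_boundaries(ev)
  list(cycles = extract_cycles(trace, b), boundaries = b,
       events = ev, envelope = env, stmht = st)
}
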