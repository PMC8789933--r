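#' Specification of a synthetic cardiac cycle
#'
#' Describes a synthetic phonocardiogram cycle: S1 and S2 are
#' Gaussian-windowed tone bursts (analytically known spectral centroids
#' inside the 20-700 Hz heart-sound band), optionally overlaid with a
#' band-limited noise murmur in the systolic and/or diastolic interval plus
#' white measurement noise. Diastole must exceed systole - the asymmetry
#' the cycle-pairing stage relies on.
#'
#' @param s1_center_hz,s2_center_hz Burst tone frequencies (Hz).
#' @param s1_dur,s2_dur Burst durations (s, ~6 sigma of the window).
#' @param s1_amp,s2_amp Burst peak amplitudes (S2 softer than S1 by
#'   default; accentuated or diminished valve-closure sounds are part of a
#'   class's auscultatory signature).
#' @param systole S1-center to S2-center interval (s).
#' @param diastole S2-center to next S1-center interval (s); must exceed
#'   `systole`.
#' @param murmur `NULL`, or `list(band = c(lo, hi), amplitude, placement)`
#'   with placement one of `"systolic"`, `"diastolic"`, `"both"`.
#' @param fs Sampling rate (Hz).
#' @param noise_sd SD of additive white noise (relative to unit burst peak).
#' @param period_jitter_sd Relative SD of per-cycle systole/diastole
#'   durations (heart-rate variability).
#' @param amp_jitter_sd Relative SD of per-burst and per-murmur amplitudes.
#' @return Object of class `cycle_spec`.
#' @export
cycle_spec <- function(s1_center_hz = 70, s2_center_hz = 120,
                       s1_dur = 0.09, s2_dur = 0.07,
                       s1_amp = 1.0, s2_amp = 0.8,
                       systole = 0.3, diastole = 0.5,
                       murmur = NULL, fs = 44100, noise_sd = 0.02,
                       period_jitter_sd = 0.03, amp_jitter_sd = 0.1) {
  if (diastole <= systole) stop("diastole must exceed systole")
  if (any(c(s1_dur, s2_dur, systole, diastole) <= 0)) stop("durations must be positive")
  if (!is.null(murmur)) {
    if (!all(c("band", "amplitude", "placement") %in% names(murmur)))
      stop("murmur needs band, amplitude and placement")
    if (murmur$band[1] <= 0 || murmur$band[2] >= fs / 2 ||
        murmur$band[1] >= murmur$band[2])
      stop("murmur band must lie within (0, fs/2)")
    if (!murmur$placement %in% c("systolic", "diastolic", "both"))
      stop("murmur placement must be systolic, diastolic or both")
  }
  structure(list(s1_center_hz = s1_center_hz, s2_center_hz = s2_center_hz,
                 s1_dur = s1_dur, s2_dur = s2_dur,
                 s1_amp = s1_amp, s2_amp = s2_amp,
                 systole = systole, diastole = diastole,
                 murmur = murmur, fs = fs, noise_sd = noise_sd,
                 period_jitter_sd = period_jitter_sd,
                 amp_jitter_sd = amp_jitter_sd),
            class = "cycle_spec")
}

# cosine-tapered mask over [from, to] seconds on an n-sample grid; the wide
# default taper gives murmurs a crescendo-decrescendo (diamond) shape that
# fades near the bursts, as ejection/regurgitant murmurs do
interval_mask <- function(n, fs, from, to, taper = 0.35) {
  t <- (seq_len(n) - 1) / fs
  w <- numeric(n)
  len <- to - from
  ramp <- taper * len
  inside <- t >= from & t <= to
  w[inside] <- 1
  up <- t >= from & t < from + ramp
  w[up] <- 0.5 * (1 - cos(pi * (t[up] - from) / ramp))
  down <- t > to - ramp & t <= to
  w[down] <- 0.5 * (1 - cos(pi * (to - t[down]) / ramp))
  w
}

#' Generate a synthetic PCG recording with ground truth
#'
#' Concatenates `n_cycles` cycles of the given spec, with one diastole of
#' silent lead-in and lead-out so that boundary events of the first and last
#' cycles fall inside the STMHT-valid region. The returned ground truth
#' lists every S1/S2 burst center.
#'
#' @param spec A [cycle_spec()].
#' @param n_cycles Number of cycles (>= 1).
#' @param seed Integer seed; identical seeds give identical recordings.
#' @return List with `trace` (a unit-peak [pcg_trace()]) and `truth`
#'   (`s1_centers`, `s2_centers` in s, plus timing constants).
#' @export
generate_recording <- function(spec, n_cycles, seed = 1) {
  stopifnot(inherits(spec, "cycle_spec"), n_cycles >= 1)
  set.seed(seed)
  fs <- spec$fs
  period <- spec$systole + spec$diastole
  lead <- spec$diastole

  # per-cycle timing with mild heart-rate variability; jitter is truncated
  # so diastole always stays longer than systole
  jit <- function(base) {
    f <- 1 + stats::rnorm(1, 0, spec$period_jitter_sd)
    base * min(max(f, 0.85), 1.15)
  }
  s1_centers <- numeric(n_cycles)
  s2_centers <- numeric(n_cycles)
  tcur <- lead
  for (i in seq_len(n_cycles)) {
    s1_centers[i] <- tcur
    s2_centers[i] <- tcur + jit(spec$systole)
    tcur <- s2_centers[i] + jit(spec$diastole)
  }
  total <- tcur - spec$systole + lead
  n <- round(total * fs)
  t <- (seq_len(n) - 1) / fs

  x <- numeric(n)
  amp_jit <- function(a) a * max(1 + stats::rnorm(1, 0, spec$amp_jitter_sd), 0.3)
  burst <- function(center, f, dur, amp) {
    s <- dur / 6
    idx <- which(abs(t - center) <= dur)
    phase <- stats::runif(1, 0, 2 * pi)
    win <- exp(-0.5 * ((t[idx] - center) / s)^2)
    x[idx] <<- x[idx] + amp * win * sin(2 * pi * f * (t[idx] - center) + phase)
  }
  for (i in seq_len(n_cycles)) {
    burst(s1_centers[i], spec$s1_center_hz, spec$s1_dur, amp_jit(spec$s1_amp))
    burst(s2_centers[i], spec$s2_center_hz, spec$s2_dur, amp_jit(spec$s2_amp))
  }

  if (!is.null(spec$murmur)) {
    m <- spec$murmur
    # random-phase multisine: spectrally flat band-limited pseudo-noise with
    # a reproducible, stable plateau (a filtered-white-noise murmur has
    # Rayleigh-fluctuating per-cycle spectra, which no real feature could
    # track); one component every ~4 Hz sounds noise-like and keeps the
    # plateau insensitive to the particular phase draw
    freqs <- seq(m$band[1], m$band[2], by = 4)
    phases <- stats::runif(length(freqs), 0, 2 * pi)
    band_noise <- rowSums(vapply(seq_along(freqs), function(j)
      sin(2 * pi * freqs[j] * t + phases[j]), numeric(n)))
    band_noise <- band_noise / max(abs(band_noise))
    mask <- numeric(n)
    next_s1 <- c(s1_centers[-1], tcur)
    for (i in seq_len(n_cycles)) {
      if (m$placement %in% c("systolic", "both")) {
        mask <- mask + amp_jit(1) * interval_mask(n, fs,
                                                  s1_centers[i] + spec$s1_dur / 2,
                                                  s2_centers[i] - spec$s2_dur / 2)
      }
      if (m$placement %in% c("diastolic", "both")) {
        mask <- mask + amp_jit(1) * interval_mask(n, fs,
                                                  s2_centers[i] + spec$s2_dur / 2,
                                                  next_s1[i] - spec$s1_dur / 2)
      }
    }
    x <- x + m$amplitude * band_noise * mask
  }
  if (spec$noise_sd > 0) x <- x + stats::rnorm(n, sd = spec$noise_sd)
  x <- x / max(abs(x))

  list(trace = pcg_trace(x, fs),
       truth = list(s1_centers = s1_centers, s2_centers = s2_centers,
                    systole = spec$systole, diastole = spec$diastole,
                    period = period, fs = fs, n_cycles = n_cycles))
}

#' Synthetic presets for the seven diagnostic classes
#'
#' Seven named [cycle_spec()]s differing in murmur band, placement and
#' amplitude so that the downstream frequency features separate the
#' classes: NM is murmur-free; the pathological classes carry murmurs whose
#' band (and hence width features and spectral gravity) is characteristic -
#' VSD a strong wide-band systolic murmur, MS a low-frequency diastolic
#' rumble, AS a harsh high-band systolic murmur, and so on.
#'
#' @param fs Sampling rate for all presets (Hz).
#' @return Named list of seven `cycle_spec`s
#'   (`MR`, `MS`, `ASD`, `NM`, `AS`, `AR`, `VSD`).
#' @export
class_presets <- function(fs = 44100) {
  list(
    MR  = cycle_spec(murmur = list(band = c(150, 350), amplitude = 0.35,
                                   placement = "both"), fs = fs),
    MS  = cycle_spec(s1_amp = 1.2,   # loud S1 of mitral stenosis
                     murmur = list(band = c(40, 90), amplitude = 0.5,
                                   placement = "diastolic"), fs = fs),
    ASD = cycle_spec(murmur = list(band = c(100, 250), amplitude = 0.35,
                                   placement = "both"), fs = fs),
    NM  = cycle_spec(fs = fs),
    AS  = cycle_spec(s2_amp = 0.75,  # diminished A2 of calcific stenosis
                     murmur = list(band = c(480, 680), amplitude = 0.35,
                                   placement = "both"), fs = fs),
    AR  = cycle_spec(murmur = list(band = c(300, 500), amplitude = 0.35,
                                   placement = "both"), fs = fs),
    VSD = cycle_spec(s2_amp = 1.15,  # accentuated P2 with pulmonary hypertension
                     murmur = list(band = c(250, 430), amplitude = 0.35,
                                   placement = "both"), fs = fs)
  )
}

# draws from N(mu, sigma) via the Cholesky factor
rmvnorm_chol <- function(n, mu, sigma) {
  d <- length(mu)
  z <- matrix(stats::rnorm(n * d), n, d)
  sweep(z %*% chol(sigma), 2, mu, "+")
}

#' Sample a labelled feature dataset from a mixture model
#'
#' Draws `n_per_class` points from each component's trivariate normal and
#' labels them, for coverage-calibration and parameter-recovery studies.
#'
#' @param model A `pcg_classifier` or `pcg_gmm` with labelled components.
#' @param n_per_class Draws per component.
#' @param seed Integer seed.
#' @return List with `features` (matrix, columns `gamma1..3`) and `labels`.
#' @export
generate_feature_dataset <- function(model, n_per_class, seed = 1) {
  stopifnot(n_per_class >= 1)
  set.seed(seed)
  K <- length(model$pi)
  feats <- do.call(rbind, lapply(seq_len(K), function(k)
    rmvnorm_chol(n_per_class, model$mu[k, ], model$sigma[[k]])))
  colnames(feats) <- paste0("gamma", seq_len(ncol(feats)))
  list(features = feats,
       labels = rep(model$labels, each = n_per_class))
}
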