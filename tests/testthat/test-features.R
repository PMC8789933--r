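test_that("magnitude spectrum matches the brute-force DFT", {
  set.seed(21)
  x <- rnorm(64)
  sp <- magnitude_spectrum(pcg_trace(x, 64))
  expect_equal(sp$values, oracle_dft(x), tolerance = 1e-8)
  expect_equal(sp$bin_hz, 1)
})

test_that("magnitude spectrum concentrates energy where expected", {
  const <- magnitude_spectrum(pcg_trace(rep(2, 100), 100))
  expect_equal(const$values[1], 200)
  expect_equal(const$values[-1], numeric(50), tolerance = 1e-9)
  tone <- magnitude_spectrum(pcg_trace(sin(2 * pi * 10 * (0:99) / 100), 100))
  expect_equal(which.max(tone$values) - 1, 10)
  expect_error(magnitude_spectrum(pcg_trace(1, 100)), "too short")
})

test_that("secondary envelope matches the literal transcription", {
  set.seed(22)
  x <- abs(rnorm(60)) + 0.5
  sp <- structure(list(values = x, bin_hz = 2, fs = 240),
                  class = "pcg_spectrum")
  env <- secondary_envelope(sp, L1 = 3, L2 = 1)
  expect_equal(env$values, oracle_secondary(x, 3, 1), tolerance = 1e-10)
  # the printed setting makes the inner window empty: pure triangular smoother
  x2 <- abs(rnorm(200)) + 0.5
  sp2 <- structure(list(values = x2, bin_hz = 1, fs = 400),
                   class = "pcg_spectrum")
  expect_equal(secondary_envelope(sp2, 9, 17)$values,
               oracle_secondary(x2, 9, 17), tolerance = 1e-10)
  # swapped reading equals the (17, 9) literal evaluation
  expect_equal(secondary_envelope(sp2, 9, 17, swap_windows = TRUE)$values,
               oracle_secondary(x2, 17, 9), tolerance = 1e-10)
})

test_that("secondary envelope is shift-invariant on constants and scale-free", {
  sp <- structure(list(values = rep(3, 100), bin_hz = 1, fs = 200),
                  class = "pcg_spectrum")
  expect_equal(secondary_envelope(sp, 9, 17)$values, rep(1, 100))
  set.seed(23)
  x <- abs(rnorm(100)) + 1
  e1 <- secondary_envelope(structure(list(values = x, bin_hz = 1, fs = 200),
                                     class = "pcg_spectrum"), 9, 17)
  e2 <- secondary_envelope(structure(list(values = 2 * x, bin_hz = 1, fs = 200),
                                     class = "pcg_spectrum"), 9, 17)
  expect_equal(e1$values, e2$values, tolerance = 1e-12)
  expect_error(secondary_envelope(structure(list(values = rep(1, 10),
                                                 bin_hz = 1, fs = 20),
                                            class = "pcg_spectrum"), 9, 17),
               "too short")
})

test_that("gravity center is the frequency-weighted mean", {
  mk <- function(v, bh) structure(list(values = v, bin_hz = bh),
                                  class = "pcg_spec_envelope")
  # symmetric envelope about bin 50
  sym <- exp(-0.5 * ((0:100 - 50) / 8)^2)
  expect_equal(gravity_center(mk(sym, 2)), 100, tolerance = 1e-9)
  # rectangle spanning 100-200 Hz at 1 Hz bins
  rect <- c(rep(0, 100), rep(1, 101), rep(0, 99))
  expect_equal(gravity_center(mk(rect, 1)), 150, tolerance = 0.5)
  set.seed(24)
  v <- abs(rnorm(80))
  expect_equal(gravity_center(mk(v, 3)),
               sum((0:79) * v) / sum(v) * 3, tolerance = 1e-12)
  expect_error(gravity_center(mk(numeric(10), 1)), "zero envelope")
})

test_that("frequency widths read outermost threshold crossings", {
  mk <- function(v, bh) structure(list(values = v, bin_hz = bh),
                                  class = "pcg_spec_envelope")
  rect <- c(rep(0, 100), rep(1, 101), rep(0, 99))
  expect_equal(unname(frequency_widths(mk(rect, 1))), c(100, 100, 100))
  # triangular peak: widths shrink as the threshold rises
  tri <- pmax(0, 1 - abs(0:200 - 100) / 80)
  w <- frequency_widths(mk(tri, 1))
  expect_true(all(diff(unname(w)) < 0))
  # Gaussian bump: width at half maximum equals 2*sigma*sqrt(2 log 2)
  g <- exp(-0.5 * ((0:400 - 200) / 30)^2)
  w5 <- frequency_widths(mk(g, 1), thv_list = 0.5)
  expect_equal(unname(w5), 2 * 30 * sqrt(2 * log(2)), tolerance = 2)
  # never-exceeded threshold gives width zero
  expect_equal(unname(frequency_widths(mk(0.4 * rect, 1), thv_list = 0.9)), 0)
  expect_error(frequency_widths(mk(rect, 1), thv_list = 1.2), "in \\(0, 1\\)")
})

test_that("widths are non-increasing in the threshold for arbitrary envelopes", {
  set.seed(25)
  for (rep_i in 1:20) {
    v <- abs(rnorm(150))
    v <- v / max(v)
    env <- structure(list(values = v, bin_hz = 1), class = "pcg_spec_envelope")
    w <- frequency_widths(env, thv_list = sort(runif(5, 0.05, 0.95)))
    expect_true(all(diff(unname(w)) <= 0))
    g <- gravity_center(env)
    expect_gte(g, 0)
    expect_lte(g, length(v) - 1)
  }
})

test_that("feature vectors reflect the segments' spectral content", {
  fs <- 2000
  t <- (0:999) / fs
  seg80 <- pcg_trace(sin(2 * pi * 80 * t) * exp(-((t - 0.25) / 0.08)^2), fs)
  seg150 <- pcg_trace(sin(2 * pi * 150 * t) * exp(-((t - 0.25) / 0.08)^2), fs)
  ff_same <- feature_vector(seg80, seg80)
  expect_equal(unname(ff_same[1:4]), unname(ff_same[5:8]))
  ff <- feature_vector(seg80, seg150)
  expect_lt(ff[["CS1_G"]], ff[["CS2_G"]])
  # wideband noise is wider than a pure tone at the lowest threshold
  set.seed(26)
  noise <- pcg_trace(rnorm(1000), fs)
  ff_n <- feature_vector(noise, seg80)
  expect_gt(ff_n[["CS1_FW1"]], ff_n[["CS2_FW1"]])
  expect_equal(names(ff), ff_feature_names())
})
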