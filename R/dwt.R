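# Periodized orthogonal multilevel DWT with the Daubechies-10 filter pair.
# Analysis uses circular convolution + dyadic downsampling; synthesis is the
# transpose of the (orthogonal) analysis operator, so reconstruction is exact
# when each level's length stays >= twice the filter length.

# Daubechies 10-vanishing-moment scaling (lowpass analysis) filter, 20 taps.
DB10_LO <- c(
  -1.3264202894521244e-05,  9.3588670320069592e-05, -1.1646685512928545e-04,
  -6.8585669495971162e-04,  1.9924052951850561e-03,  1.3953517470529011e-03,
  -1.0733175483330575e-02,  3.6065535669561697e-03,  3.3212674059341002e-02,
  -2.9457536821875813e-02, -7.1394147166397082e-02,  9.3057364603572348e-02,
   1.2736934033579325e-01, -1.9594627437737705e-01, -2.4984642432731538e-01,
   2.8117234366057747e-01,  6.8845903945360354e-01,  5.2720118893172563e-01,
   1.8817680007769150e-01,  2.6670057900555554e-02
)

db10_filters <- function() {
  h <- DB10_LO
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)   # quadrature-mirror highpass
  list(h = h, g = g)
}

dwt_step <- function(x, h, g) {
  M <- length(x)
  half <- M %/% 2L
  L <- length(h)
  a <- numeric(half)
  d <- numeric(half)
  base <- 2L * (seq_len(half) - 1L)
  for (n in seq_len(L)) {
    idx <- (base + (n - 1L)) %% M + 1L
    a <- a + h[n] * x[idx]
    d <- d + g[n] * x[idx]
  }
  list(a = a, d = d)
}

idwt_step <- function(a, d, h, g) {
  half <- length(a)
  M <- 2L * half
  L <- length(h)
  x <- numeric(M)
  base <- 2L * (seq_len(half) - 1L)
  for (n in seq_len(L)) {
    idx <- (base + (n - 1L)) %% M + 1L
    contrib <- h[n] * a + g[n] * d
    x[idx] <- x[idx] + contrib
  }
  x
}

#' Multilevel db10 wavelet decomposition (periodized)
#'
#' @param x Numeric vector; padded internally to a multiple of `2^levels`.
#' @param levels Number of dyadic decomposition levels.
#' @return List with `approx` (deepest approximation), `details` (list,
#'   level 1 = finest), `n` (original length) and `levels`.
#' @keywords internal
dwt_multilevel <- function(x, levels) {
  f <- db10_filters()
  n <- length(x)
  block <- 2L^levels
  pad <- (block - n %% block) %% block
  x <- c(x, numeric(pad))
  details <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    if (length(a) < 2L * length(f$h)) {
      levels <- j - 1L
      details <- details[seq_len(levels)]
      break
    }
    s <- dwt_step(a, f$h, f$g)
    details[[j]] <- s$d
    a <- s$a
  }
  list(approx = a, details = details, n = n, levels = levels)
}

#' Reconstruct from a multilevel db10 decomposition
#' @param dec Result of [dwt_multilevel()], possibly with zeroed bands.
#' @keywords internal
idwt_multilevel <- function(dec) {
  f <- db10_filters()
  a <- dec$approx
  for (j in rev(seq_len(dec$levels))) {
    a <- idwt_step(a, dec$details[[j]], f$h, f$g)
  }
  a[seq_len(dec$n)]
}
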