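# Literal nested-loop transcriptions of the defining equations, used as
# independent oracles for the vectorized implementations. Indices follow
# the printed 0-based conventions; R offsets are applied at subscript time.

# windowed local-variance envelope, normalized to unit maximum,
# borders edge-replicated
oracle_viola <- function(x, W) {
  M <- length(x)
  raw <- rep(NA_real_, M)
  for (m in W:(M - 1 - W)) {            # 0-based center
    mbar <- 0
    for (k in (m - W):(m + W)) mbar <- mbar + x[k + 1]
    mbar <- mbar / (2 * W + 1)
    s <- 0
    for (k in (m - W):(m + W)) s <- s + (x[k + 1] - mbar)^2
    raw[m + 1] <- s / (2 * W + 1)
  }
  raw[1:W] <- raw[W + 1]
  raw[(M - W + 1):M] <- raw[M - W]
  raw / max(raw)
}

# sliding antisymmetric-kernel transform, zero borders
oracle_stmht <- function(env, N) {
  M <- length(env)
  half <- (N - 1) %/% 2
  k <- numeric(N)
  for (i in 0:(N - 1)) {
    a <- N - 1 - 2 * i
    if (i == half) k[i + 1] <- 0
    else k[i + 1] <- (cos(a * pi / (2 * N)) - cos(a * pi / 2)) /
        (N * sin(a * pi / (2 * N)))
  }
  out <- numeric(M)
  for (n in half:(M - 1 - half)) {
    s <- 0
    for (i in 0:(N - 1)) s <- s + env[n - half + i + 1] * k[i + 1]
    out[n + 1] <- s
  }
  out
}

# O(M^2) magnitude DFT restricted to the half spectrum
oracle_dft <- function(x) {
  M <- length(x)
  vapply(0:(M %/% 2), function(kk) {
    s <- 0 + 0i
    for (m in 0:(M - 1)) s <- s + x[m + 1] * exp(-2i * pi * kk * m / M)
    Mod(s)
  }, numeric(1))
}

# double-window smoothing of a half spectrum with reflected padding,
# clamped at zero and normalized to unit maximum
oracle_secondary <- function(x, L1, L2) {
  n <- length(x)
  pad <- L1 + L2
  xp <- c(rev(x[2:(pad + 1)]), x, rev(x[(n - pad):(n - 1)]))
  out <- numeric(n)
  r <- L1 - L2 - 1
  for (kk in seq_len(n)) {
    c0 <- kk + pad                       # position of bin kk in xp
    s1 <- 0
    for (l1 in -(L1 + L2):(L1 + L2))
      s1 <- s1 + (L1 + L2 + 1 - abs(l1)) * xp[c0 + l1]
    s2 <- 0
    if (r >= 0) for (l2 in -r:r) s2 <- s2 + xp[c0 + l2]
    out[kk] <- (s1 - s2) / ((2 * L1 + 1) * (2 * L2 + 1))
  }
  out[out < 0] <- 0
  out / max(out)
}

# elementwise standardize-and-dot projection
oracle_project <- function(ff, mu, sigma, vectors, m) {
  g <- numeric(m)
  for (i in seq_len(m)) {
    s <- 0
    for (j in seq_along(ff)) s <- s + (ff[j] - mu[j]) / sigma[j] * vectors[j, i]
    g[i] <- s
  }
  g
}
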