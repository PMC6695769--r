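# Shared fixtures, generated in code at test time.

defaultWorld <- local({
  cache <- NULL
  function(seed = 7L) {
    if (is.null(cache)) cache <<- simulateWorld(runConfig(seed = seed))
    cache
  }
})

# A deterministic pseudo-random spectrum-like vector.
randomSpectrum <- function(p = 215, seed = 1) {
  set.seed(seed)
  base <- 0.3 + 0.6 * exp(-((seq_len(p) - p / 3) / (p / 6))^2)
  base + rnorm(p, sd = 0.02)
}

# Independent brute-force Savitzky-Golay: refit the window polynomial at
# every channel and differentiate analytically. Edge channels evaluate the
# nearest full window's polynomial at the edge offsets.
bruteSavgol <- function(y, window, polyorder, deriv, step = 1) {
  n <- length(y)
  h <- (window - 1) / 2
  out <- numeric(n)
  for (j in seq_len(n)) {
    c0 <- min(max(j, h + 1), n - h)       # centre of nearest full window
    idx <- (c0 - h):(c0 + h)
    xs <- (idx - c0) * step
    fit <- lm(y[idx] ~ stats::poly(xs, polyorder, raw = TRUE))
    cf <- coef(fit)
    x0 <- (j - c0) * step                 # evaluation offset from centre
    val <- 0
    for (k in deriv:polyorder) {
      ck <- cf[k + 1]
      if (is.na(ck)) next
      val <- val + ck * factorial(k) / factorial(k - deriv) * x0^(k - deriv)
    }
    out[j] <- val
  }
  out
}
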