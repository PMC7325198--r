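# Independent oracles and small fixture builders shared across tests.

# Naive double-sum cross-correlation: C[k] = step * sum_i f[i] g[i+k] for
# k = -(N-1) .. N-1, evaluated lag by lag. Independent of the FFT path.
corr_naive <- function(f, g, step) {
  n <- length(f)
  vapply(seq(-(n - 1), n - 1), function(k) {
    i <- seq_len(n)
    j <- i + k
    ok <- j >= 1 & j <= n
    step * sum(f[i[ok]] * g[j[ok]])
  }, numeric(1))
}

# Naive CCS from the double-sum correlation.
ccs_naive <- function(standard, sample, mode = "windowed", max_lag = 0.5,
                      square = TRUE) {
  f <- if (square) standard$intensity^2 else standard$intensity
  g <- if (square) sample$intensity^2 else sample$intensity
  step <- standard$meta$step
  cfg <- corr_naive(f, g, step)
  cff <- corr_naive(f, f, step)
  lags <- step * seq(-(length(f) - 1), length(f) - 1)
  keep <- if (mode == "full") rep(TRUE, length(lags)) else abs(lags) <= max_lag
  sum(cfg[keep]) / sum(cff[keep])
}

# Random positive pattern on a uniform grid (not simulator-based, so the
# simulator is never its own oracle).
random_pattern <- function(n, step = 0.019, start = 5, label = "rand") {
  xrd_pattern(start + step * (seq_len(n) - 1), stats::rexp(n), label = label)
}

# A pattern with a single nonzero point, for delta-function correlations.
delta_pattern <- function(n, at, value = 1, step = 0.019, start = 5) {
  y <- numeric(n)
  y[at] <- value
  xrd_pattern(start + step * (seq_len(n) - 1), y)
}

# Noise-free, background-free render settings.
clean_config <- function(...) {
  sim_config(bg_coeffs = 0, noise_scale = 0, ...)
}
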