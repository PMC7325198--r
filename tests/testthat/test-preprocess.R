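# Preprocessing stages: resampling, background, smoothing, K-alpha2
# stripping, normalization.

grid_pattern <- function(start = 10, stop = 20, step = 0.019, f = function(x) x) {
  tt <- seq(start, stop, by = step)
  xrd_pattern(tt, f(tt))
}

test_that("resample interpolates linearly and respects range limits", {
  p <- grid_pattern(f = function(x) 3 * x + 1)
  # identity on the pattern's own grid
  q <- resample(p, min(p$two_theta), max(p$two_theta), p$meta$step)
  expect_equal(q$intensity, p$intensity, tolerance = 1e-12)
  # halving the step keeps values at original nodes; midpoints of a linear
  # ramp equal the mean of their neighbours (closed form of linear interp)
  h <- resample(p, min(p$two_theta), max(p$two_theta), p$meta$step / 2)
  expect_equal(h$intensity[seq(1, length(h$intensity), by = 2)], p$intensity,
               tolerance = 1e-12)
  mids <- h$intensity[seq(2, length(h$intensity) - 1, by = 2)]
  expect_equal(mids, (p$intensity[-length(p$intensity)] + p$intensity[-1]) / 2,
               tolerance = 1e-12)
  expect_error(resample(p, 9, 20, 0.019), class = "xrd_range_error")
})

test_that("iterative-clipping background recovers known baselines", {
  params <- preprocess_params(bg_degree = 3)
  # a pure degree-3 polynomial is a fixed point of the clipping iteration
  p <- grid_pattern(f = function(x) 500 + 2 * x - 0.1 * x^2 + 0.002 * x^3)
  bg <- fit_background(p, params)
  expect_lt(max(abs(bg$intensity - p$intensity) / abs(p$intensity)), 1e-6)

  z <- grid_pattern(f = function(x) rep(0, length(x)))
  expect_equal(fit_background(z, params)$intensity, z$intensity,
               tolerance = 1e-12)

  # constant 100-count background + one pseudo-Voigt peak: truth is known
  ph <- xrd_phase("one", 30, 100)
  p2 <- render_pattern(ph, sim_config(bg_coeffs = 100, noise_scale = 0,
                                      doublet = FALSE))
  bg2 <- fit_background(p2, preprocess_params())
  expect_lt(sqrt(mean((bg2$intensity - 100)^2)), 2)
  # subtraction then clips at zero and removes the baseline
  sub <- subtract_background(p2, bg2)
  expect_gte(min(sub$intensity), 0)
})

test_that("subtract_background clips at zero and checks grids", {
  p <- grid_pattern(f = function(x) sin(x) + 2)
  expect_equal(subtract_background(p, p)$intensity,
               rep(0, length(p$two_theta)))
  zero <- grid_pattern(f = function(x) rep(0, length(x)))
  expect_equal(subtract_background(p, zero)$intensity, p$intensity)
  other <- grid_pattern(start = 11, stop = 21)
  expect_error(subtract_background(p, other), class = "xrd_grid_mismatch")
})

test_that("Savitzky-Golay smoothing reproduces low-order polynomials and reduces noise", {
  params <- preprocess_params(smooth_window = 11, smooth_order = 2)
  lin <- grid_pattern(f = function(x) 5 * x - 2)
  expect_lt(max(abs(smooth_pattern(lin, params)$intensity - lin$intensity)),
            1e-9)
  quad <- grid_pattern(f = function(x) x^2 - 30 * x + 1)
  expect_lt(max(abs(smooth_pattern(quad, params)$intensity - quad$intensity)),
            1e-9)
  set.seed(7)
  tt <- seq(5, 60, by = 0.019)
  noisy <- xrd_pattern(tt, 100 + rnorm(length(tt), 0, 10))
  sm <- smooth_pattern(noisy, params)
  expect_lt(sd(sm$intensity), 10)
  short <- grid_pattern(stop = 10.14)  # 8 points < window
  expect_error(smooth_pattern(short, params), class = "xrd_window_too_large")
})

test_that("K-alpha2 stripping removes the doublet companion", {
  params <- preprocess_params()
  ph <- xrd_phase("doublet", 30, 100, ref_wavelength = params$lambda1)
  on <- render_pattern(ph, clean_config())
  off <- render_pattern(ph, clean_config(doublet = FALSE))
  stripped <- strip_kalpha2(on, params)

  pos2 <- convert_two_theta(30, params$lambda1, params$lambda2)
  i2 <- which.min(abs(on$two_theta - pos2))
  ka2_height <- on$intensity[i2] - off$intensity[i2]
  residual <- abs(stripped$intensity[i2] - off$intensity[i2])
  expect_lt(residual, 0.05 * ka2_height)

  # ratio 0 is the identity; all-zero stays all-zero
  expect_equal(strip_kalpha2(on, preprocess_params(kalpha_ratio = 0))$intensity,
               on$intensity)
  z <- grid_pattern(start = 5, stop = 60, f = function(x) rep(0, length(x)))
  expect_equal(strip_kalpha2(z, params)$intensity, z$intensity)

  # mass-reducing, and removes ~ r/(1+r) of an isolated doublet's mass
  expect_lte(sum(stripped$intensity), sum(on$intensity))
  removed <- sum(on$intensity) - sum(stripped$intensity)
  r <- params$kalpha_ratio
  expect_equal(removed / sum(on$intensity), r / (1 + r), tolerance = 0.05)
})

test_that("normalization modes, idempotence and scale invariance", {
  p <- grid_pattern(f = function(x) 2 + sin(x)^2)
  um <- normalize_pattern(p)
  expect_equal(max(um$intensity), 1)
  expect_equal(normalize_pattern(um)$intensity, um$intensity)  # idempotent
  scaled <- xrd_pattern(p$two_theta, 7 * p$intensity)
  expect_equal(normalize_pattern(scaled)$intensity, um$intensity,
               tolerance = 1e-12)
  ua <- normalize_pattern(p, preprocess_params(norm_mode = "unit_area"))
  expect_equal(sum(ua$intensity) * ua$meta$step, 1, tolerance = 1e-12)
  z <- grid_pattern(f = function(x) rep(0, length(x)))
  expect_error(normalize_pattern(z), class = "xrd_zero_pattern")
})

test_that("the full pipeline maps valid patterns to valid patterns on the same grid", {
  lib <- fixture_library(3, seed = 11)
  for (ph in lib) {
    raw <- render_pattern(ph, sim_config(seed = 5))
    pp <- preprocess(raw)
    expect_s3_class(pp, "xrd_pattern")
    expect_identical(pp$two_theta, raw$two_theta)
    expect_true(all(is.finite(pp$intensity)))
    expect_equal(max(pp$intensity), 1)
    expect_gte(min(pp$intensity), 0)
  }
})
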