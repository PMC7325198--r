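# Synthetic diffractogram generator.

test_that("render produces calibrated pseudo-Voigt profiles", {
  # zero reflections, zero background, no noise: all-zero pattern
  empty <- xrd_phase("none", numeric(0), numeric(0))
  p0 <- render_pattern(empty, clean_config())
  expect_true(all(p0$intensity == 0))

  # single Gaussian (eta = 0): apex within half a step, half height at FWHM/2
  ph <- xrd_phase("one", 30, 100, ref_wavelength = 1.540562)
  p <- render_pattern(ph, clean_config(eta = 0, doublet = FALSE))
  apex <- p$two_theta[which.max(p$intensity)]
  expect_lte(abs(apex - 30), 0.019 / 2)
  h_apex <- max(p$intensity)
  h_half <- approx(p$two_theta, p$intensity, xout = c(30 - 0.05, 30 + 0.05))$y
  expect_equal(h_half, rep(h_apex / 2, 2), tolerance = 0.01 * h_apex)

  # K-alpha2 companion at the Bragg-shifted position with ratio 0.5 height
  pon <- render_pattern(ph, clean_config())
  poff <- render_pattern(ph, clean_config(doublet = FALSE))
  pos2 <- 2 * asin((1.544398 / 1.540562) * sin(30 * pi / 360)) * 180 / pi
  companion <- pon$intensity - poff$intensity
  i2 <- which.max(companion)
  expect_lte(abs(pon$two_theta[i2] - pos2), 0.019)
  expect_equal(max(companion) / max(poff$intensity), 0.5, tolerance = 0.02)

  # out-of-range reflections are skipped with a warning
  far <- xrd_phase("far", c(30, 90), c(100, 50))
  expect_warning(render_pattern(far, clean_config()),
                 class = "xrd_reflection_out_of_range")
})

test_that("rendering is deterministic and linear", {
  ph <- xrd_phase("p", c(12, 24), c(100, 50))
  cfg <- sim_config(seed = 77)
  expect_identical(render_pattern(ph, cfg)$intensity,
                   render_pattern(ph, cfg)$intensity)

  # linearity: a two-reflection render is the sum of single-reflection
  # renders (each single phase is rescaled to 100, so scale back down)
  a <- render_pattern(xrd_phase("a", 12, 100), clean_config())
  b <- render_pattern(xrd_phase("b", 24, 100), clean_config())
  both <- render_pattern(xrd_phase("ab", c(12, 24), c(100, 50)),
                         clean_config())
  expect_lt(max(abs(both$intensity - (a$intensity + 0.5 * b$intensity))),
            1e-9)
})

test_that("Poisson noise has the configured variance", {
  # flat background b with noise_scale s: counts ~ Poisson(s*b), var = s*b
  flat <- xrd_phase("flat", numeric(0), numeric(0))
  s <- 3; b <- 50
  p <- render_pattern(flat, sim_config(start = 5, stop = 300, step = 0.019,
                                       bg_coeffs = b, noise_scale = s,
                                       seed = 8))
  expect_gt(length(p$intensity), 1e4)
  expect_equal(var(p$intensity), s * b, tolerance = 0.05 * s * b)
  expect_equal(mean(p$intensity), s * b, tolerance = 0.02 * s * b)
})

test_that("perturb_intensities moves intensities but never positions", {
  ph <- fixture_library(2, seed = 3)[[1]]
  expect_identical(perturb_intensities(ph, 0), ph)
  p1 <- perturb_intensities(ph, 0.5, seed = 10)
  p2 <- perturb_intensities(ph, 0.5, seed = 10)
  expect_identical(p1, p2)
  expect_identical(p1$reflections$position, ph$reflections$position)
  expect_equal(max(p1$reflections$rel_intensity), 100)
  expect_false(isTRUE(all.equal(p1$reflections$rel_intensity,
                                ph$reflections$rel_intensity)))
})

test_that("mix_patterns is a weighted pointwise sum", {
  cfg <- clean_config()
  a <- render_pattern(xrd_phase("a", 15, 100), cfg)
  expect_equal(mix_patterns(list(a), 1)$intensity, a$intensity)

  z <- xrd_pattern(a$two_theta, rep(0, length(a$two_theta)))
  expect_true(all(mix_patterns(list(z, z), c(0.5, 0.5))$intensity == 0))

  expect_error(mix_patterns(list(a, z), c(0.4, 0.4)),
               class = "xrd_bad_weights")

  # 0.3 active + 0.7 diluent: strongest lines of both phases are detected
  lib <- fixture_library(4, seed = 19)
  act <- render_pattern(lib[[3]], cfg)
  dil <- render_pattern(lib[[4]], cfg)
  mixed <- mix_patterns(list(act, dil), c(0.3, 0.7))
  pk <- detect_peaks(preprocess(mixed))
  top_of <- function(ph) {
    r <- ph$reflections
    convert_two_theta(r$position[which.max(r$rel_intensity)],
                      ph$ref_wavelength_angstrom, 1.540562)
  }
  expect_true(any(abs(pk$peaks$position - top_of(lib[[3]])) <= 0.05))
  expect_true(any(abs(pk$peaks$position - top_of(lib[[4]])) <= 0.05))
})

test_that("unrelated_phases rejects phases with coincident strong lines", {
  target <- xrd_phase("t", c(15.0, 25.0, 40.0), c(100, 60, 20))
  pool <- list(
    coincident = xrd_phase("coincident", c(15.3, 33.0), c(90, 100)),
    weak_coincident = xrd_phase("weak_coincident", c(15.3, 33.0), c(8, 100)),
    clear = xrd_phase("clear", c(10.0, 33.0, 50.0), c(100, 80, 40)))
  sel <- unrelated_phases(pool, target, 2)
  expect_equal(unname(vapply(sel, function(p) p$name, character(1))),
               c("weak_coincident", "clear"))
  expect_error(unrelated_phases(pool, target, 3), class = "xrd_bad_params")
})

test_that("fixture libraries are reproducible with a designed similar pair", {
  libA <- fixture_library(6, seed = 42)
  libB <- fixture_library(6, seed = 42)
  expect_identical(libA, libB)
  expect_length(libA, 6)

  # the designed pair shares >= 40% of phase 1's positions within 0.05 deg
  p1 <- libA[[1]]$reflections$position
  p2 <- libA[[2]]$reflections$position
  shared <- sum(vapply(p1, function(x) any(abs(p2 - x) <= 0.05), logical(1)))
  expect_gte(shared / length(p1), 0.4)

  # no two phases are identical in position set
  for (i in 1:5) for (j in (i + 1):6) {
    pi <- libA[[i]]$reflections$position
    pj <- libA[[j]]$reflections$position
    overlap <- sum(vapply(pi, function(x) any(abs(pj - x) <= 0.05),
                          logical(1)))
    expect_lt(overlap, max(length(pi), length(pj)))
  }
})
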