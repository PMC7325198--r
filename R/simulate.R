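# Synthetic diffractogram generator: the test substrate for the whole
# pipeline. Emulates a Bragg-Brentano laboratory instrument with a Cu tube:
# pseudo-Voigt reflections, the K-alpha1/2 doublet, a smooth polynomial
# background, Poisson counting noise, and preferred-orientation-style
# relative-intensity perturbation.

#' Simulation configuration
#'
#' Defaults reproduce a typical forensic bench measurement: 5-60 degrees
#' 2-theta at a 0.019-degree step, Cu K-alpha doublet
#' (1.540562 / 1.544398 A, intensity ratio 0.5), peak FWHM 0.1 degrees,
#' half-Lorentzian pseudo-Voigt shape, a flat background and Poisson
#' counting statistics with ten expected counts per unit intensity, so a
#' strongest reflection of relative intensity 100 accumulates several
#' thousand counts at its apex — typical for a benchtop instrument counting
#' one second per step on a crystalline organic.
#'
#' @param start,stop,step angular grid, degrees 2-theta.
#' @param fwhm full width at half maximum of every peak, degrees 2-theta
#'   (must be at least `2 * step`).
#' @param eta pseudo-Voigt mixing fraction in `[0, 1]` (0 = Gaussian,
#'   1 = Lorentzian).
#' @param doublet render the K-alpha2 companion of every reflection.
#' @param lambda1,lambda2 K-alpha1 / K-alpha2 wavelengths, Angstrom.
#' @param kalpha_ratio K-alpha2 : K-alpha1 intensity ratio.
#' @param bg_coeffs polynomial background coefficients, ascending powers of
#'   2-theta, in counts.
#' @param noise_scale expected counts at unit intensity; 0 disables noise.
#' @param intensity_sigma log-scale standard deviation of per-peak intensity
#'   perturbation used by [perturb_intensities()].
#' @param seed integer seed for noise and perturbation; `NULL` uses the
#'   ambient RNG stream.
#' @return a list of class `xrd_sim_config`.
#' @export
sim_config <- function(start = 5, stop = 60, step = 0.019, fwhm = 0.1,
                       eta = 0.5, doublet = TRUE, lambda1 = 1.540562,
                       lambda2 = 1.544398, kalpha_ratio = 0.5,
                       bg_coeffs = 100, noise_scale = 10,
                       intensity_sigma = 0.5, seed = NULL) {
  if (!(start < stop) || step <= 0)
    xrd_error("bad_params", "need start < stop and step > 0")
  if (fwhm < 2 * step)
    xrd_error("bad_params", "fwhm must be at least 2 * step")
  if (eta < 0 || eta > 1) xrd_error("bad_params", "eta must lie in [0, 1]")
  if (noise_scale < 0 || intensity_sigma < 0)
    xrd_error("bad_params", "noise_scale and intensity_sigma must be >= 0")
  if (!(lambda2 > lambda1 && lambda1 > 0))
    xrd_error("bad_params", "need lambda2 > lambda1 > 0")
  structure(list(start = start, stop = stop, step = step, fwhm = fwhm,
                 eta = eta, doublet = doublet, lambda1 = lambda1,
                 lambda2 = lambda2, kalpha_ratio = kalpha_ratio,
                 bg_coeffs = bg_coeffs, noise_scale = noise_scale,
                 intensity_sigma = intensity_sigma, seed = seed),
            class = "xrd_sim_config")
}

# Unit-area pseudo-Voigt profile at positions x, centre x0. Far Gaussian
# tails are flushed to exact zero: subnormal tail values carry no signal but
# make every later vector operation on the pattern dramatically slower.
pseudo_voigt <- function(x, x0, fwhm, eta) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  gamma <- fwhm / 2
  z2 <- ((x - x0) / sigma)^2
  gauss <- exp(-0.5 * pmin(z2, 1380)) / (sigma * sqrt(2 * pi))
  gauss[z2 >= 1380] <- 0
  lorentz <- gamma / (pi * ((x - x0)^2 + gamma^2))
  (1 - eta) * gauss + eta * lorentz
}

#' Render a phase as a synthetic diffractogram
#'
#' Each reflection contributes a pseudo-Voigt profile whose area (not
#' height) is proportional to its relative intensity, so mixtures remain
#' weight-interpretable. Reflection positions are converted from the phase's
#' reference wavelength to the instrument K-alpha1 wavelength via Bragg's
#' law; with `doublet = TRUE` a K-alpha2 companion with `kalpha_ratio` times
#' the area is added at its Bragg-shifted position. A polynomial background
#' is added, and with `noise_scale > 0` the returned intensities are Poisson
#' counts with mean `noise_scale` times the noise-free signal.
#'
#' @param phase an [xrd_phase()].
#' @param config an [sim_config()].
#' @return an [xrd_pattern()] labelled with the phase name; its wavelength
#'   is `config$lambda1`.
#' @export
render_pattern <- function(phase, config = sim_config()) {
  if (!inherits(phase, "xrd_phase"))
    xrd_error("parse_error", "phase is not an xrd_phase")
  grid <- seq(config$start, config$stop, by = config$step)
  y <- polyval_asc(config$bg_coeffs, grid)
  if (any(y < 0)) xrd_error("bad_params", "background must be nonnegative")
  pos <- convert_two_theta(phase$reflections$position,
                           phase$ref_wavelength_angstrom, config$lambda1)
  for (k in seq_len(nrow(phase$reflections))) {
    a <- phase$reflections$rel_intensity[k]
    if (pos[k] < config$start || pos[k] > config$stop) {
      xrd_warning("reflection_out_of_range",
                  sprintf("reflection at %.3f deg outside grid; skipped",
                          pos[k]))
      next
    }
    y <- y + a * pseudo_voigt(grid, pos[k], config$fwhm, config$eta)
    if (config$doublet) {
      p2 <- convert_two_theta(pos[k], config$lambda1, config$lambda2)
      if (p2 >= config$start && p2 <= config$stop)
        y <- y + config$kalpha_ratio * a *
          pseudo_voigt(grid, p2, config$fwhm, config$eta)
    }
  }
  if (config$noise_scale > 0)
    y <- with_seed(config$seed,
                   as.numeric(stats::rpois(length(y), config$noise_scale * y)))
  xrd_pattern(grid, y, wavelength = config$lambda1, label = phase$name)
}

#' Perturb a phase's relative intensities
#'
#' Multiplies each relative intensity by an independent lognormal factor
#' with median 1 and log-scale standard deviation `sigma`, then rescales so
#' the strongest reflection is 100. Positions are untouched: this emulates
#' crystal-habit and grinding effects (preferred orientation), which change
#' relative intensities but never peak positions.
#'
#' @param phase an [xrd_phase()].
#' @param sigma log-scale standard deviation (>= 0).
#' @param seed integer seed; `NULL` uses the ambient RNG stream.
#' @return a perturbed [xrd_phase()].
#' @export
perturb_intensities <- function(phase, sigma, seed = NULL) {
  if (sigma < 0) xrd_error("bad_params", "sigma must be >= 0")
  if (sigma == 0) return(phase)
  n <- nrow(phase$reflections)
  fac <- with_seed(seed, exp(stats::rnorm(n, 0, sigma)))
  xrd_phase(phase$name, phase$reflections$position,
            phase$reflections$rel_intensity * fac,
            ref_wavelength = phase$ref_wavelength_angstrom)
}

#' Mix patterns pointwise
#'
#' Weighted sum of patterns on a common grid; models street-sample blends
#' of an active substance with diluents (heroin samples, for instance,
#' rarely contain more than 30 percent of the active compound).
#'
#' @param patterns list of patterns on identical grids.
#' @param weights positive weights summing to 1.
#' @return mixed [xrd_pattern()].
#' @export
mix_patterns <- function(patterns, weights) {
  if (length(patterns) == 0) xrd_error("bad_params", "no patterns to mix")
  if (length(weights) != length(patterns) || any(weights <= 0) ||
      abs(sum(weights) - 1) > 1e-9)
    xrd_error("bad_weights", "weights must be positive and sum to 1")
  for (p in patterns) {
    if (!is_xrd_pattern(p)) xrd_error("parse_error", "inputs must be xrd_pattern")
    if (!same_grid(patterns[[1]], p))
      xrd_error("grid_mismatch", "patterns must share a common grid")
  }
  y <- Reduce(`+`, Map(function(p, w) w * p$intensity, patterns, weights))
  lab <- paste(vapply(patterns, function(p) p$meta$label, character(1)),
               collapse = " + ")
  pattern_with(patterns[[1]], y, label = lab)
}

#' Generate a reproducible fixture phase library
#'
#' Builds `n_phases` synthetic reference phases, each with 8-25 reflections
#' placed uniformly in `[start + 1, stop - 1]` with at least `min_sep`
#' separation and lognormal relative intensities floored at 10 (reference
#' cards tabulate reflections down to roughly that level). Phases 1 and 2
#' are a
#' deliberately similar pair sharing half of phase 1's positions — a stress
#' case mimicking structurally related designer-drug analogs.
#'
#' @param n_phases number of phases (>= 2).
#' @param seed integer seed.
#' @param start,stop angular range for reflection placement, degrees 2-theta.
#' @param min_sep minimum separation between reflections of one phase.
#' @return a named list of [xrd_phase()] objects with attribute
#'   `similar_pair = c(1, 2)`.
#' @export
fixture_library <- function(n_phases, seed = 1, start = 5, stop = 60,
                            min_sep = 0.3) {
  if (n_phases < 2) xrd_error("bad_params", "n_phases must be >= 2")
  with_seed(seed, {
    draw_positions <- function(n, fixed = numeric(0)) {
      pos <- fixed
      tries <- 0
      while (length(pos) < n && tries < 10000) {
        cand <- stats::runif(1, start + 1, stop - 1)
        if (!length(pos) || min(abs(pos - cand)) >= min_sep)
          pos <- c(pos, cand)
        tries <- tries + 1
      }
      sort(pos)
    }
    phases <- vector("list", n_phases)
    for (i in seq_len(n_phases)) {
      n_refl <- sample(8:25, 1)
      fixed <- numeric(0)
      if (i == 2) {
        p1 <- phases[[1]]$reflections$position
        fixed <- sort(sample(p1, ceiling(length(p1) / 2)))
        n_refl <- max(n_refl, length(fixed) + 4)
      }
      pos <- draw_positions(n_refl, fixed)
      # reference-card style intensities: lognormal spread, floored at 10%
      # relative intensity (weaker reflections are not tabulated on cards
      # and are unreliable identification features at bench SNR)
      rel <- exp(stats::rnorm(length(pos), 0, 1))
      rel <- pmax(100 * rel / max(rel), 10)
      phases[[i]] <- xrd_phase(sprintf("phase_%02d", i), pos, rel)
    }
    names(phases) <- vapply(phases, function(p) p$name, character(1))
    attr(phases, "similar_pair") <- c(1L, 2L)
    phases
  })
}

#' Select phases unrelated to a target phase
#'
#' Two substances are spectroscopically unrelated when their strong
#' reflections do not coincide: a lag-windowed cross-correlation score of
#' squared unit-max patterns is dominated by the strongest lines, and a
#' coincident line pair with relative intensities \eqn{r_1, r_2} contributes
#' about \eqn{(r_1 r_2 / 100^2)^2} to the score of two otherwise disjoint
#' patterns. This filter therefore rejects any pool phase that has a
#' reflection within `min_sep` of a target reflection when the product of
#' the two relative intensities exceeds `max_product` — the condition an
#' "unrelated compounds" comparison set must satisfy for the score to
#' separate substances.
#'
#' @param pool list of candidate [xrd_phase()] objects.
#' @param target the reference [xrd_phase()].
#' @param n number of phases to return.
#' @param min_sep coincidence distance, degrees 2-theta (default 0.6, the
#'   default score window plus one peak FWHM).
#' @param max_product largest allowed product of relative intensities for a
#'   coincident line pair (default 1000, i.e. a coincident pair may
#'   contribute at most about 0.01 to the score).
#' @return a list of `n` phases from `pool`, in pool order.
#' @export
unrelated_phases <- function(pool, target, n, min_sep = 0.6,
                             max_product = 1000) {
  tr <- target$reflections
  ok <- vapply(pool, function(ph) {
    pr <- ph$reflections
    for (k in seq_len(nrow(pr))) {
      near <- abs(tr$position - pr$position[k]) <= min_sep
      if (any(near &
              tr$rel_intensity * pr$rel_intensity[k] > max_product))
        return(FALSE)
    }
    TRUE
  }, logical(1))
  if (sum(ok) < n)
    xrd_error("bad_params",
              sprintf("only %d of %d pool phases are unrelated to '%s'",
                      sum(ok), length(pool), target$name))
  pool[ok][seq_len(n)]
}
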