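# Preprocessing pipeline: resample -> background -> smooth -> K-alpha2
# stripping -> normalization. Every stage maps a valid pattern to a valid
# pattern on the same grid, so stages can be toggled individually.

#' Preprocessing parameters
#'
#' Bundles the tunables of the preprocessing pipeline.
#'
#' Defaults: background polynomial degree 5 with iterative clipping
#' (tolerance 1e-6, at most 100 iterations); Savitzky-Golay window of 11
#' points (about 0.2 degrees on a 0.019-degree grid, below typical peak
#' FWHM) and order 3; the standard Cu K-alpha doublet constants
#' (lambda1 = 1.540562 A, lambda2 = 1.544398 A, intensity ratio 0.5);
#' unit-maximum normalization. Unit-max is the default because unit-area
#' normalization makes the full-lag cross-correlation score of any two
#' patterns collapse to a constant (see the methods vignette).
#'
#' @param bg_degree degree of the background polynomial (>= 0).
#' @param bg_max_iter iteration cap for background clipping.
#' @param bg_tol relative convergence tolerance for the background curve.
#' @param smooth_window Savitzky-Golay window, odd number of points.
#' @param smooth_order Savitzky-Golay polynomial order, < `smooth_window`.
#' @param lambda1,lambda2 K-alpha1 / K-alpha2 wavelengths, Angstrom.
#' @param kalpha_ratio K-alpha2 : K-alpha1 intensity ratio, in `[0, 1]`.
#' @param norm_mode `"unit_max"` (peak maximum scaled to 1) or `"unit_area"`
#'   (integral scaled to 1).
#' @return a list of class `xrd_preprocess_params`.
#' @export
preprocess_params <- function(bg_degree = 5, bg_max_iter = 100, bg_tol = 1e-6,
                              smooth_window = 11, smooth_order = 3,
                              lambda1 = 1.540562, lambda2 = 1.544398,
                              kalpha_ratio = 0.5,
                              norm_mode = c("unit_max", "unit_area")) {
  norm_mode <- match.arg(norm_mode)
  if (bg_degree < 0 || bg_degree != round(bg_degree))
    xrd_error("bad_params", "bg_degree must be a nonnegative integer")
  if (smooth_window %% 2 != 1 || smooth_window <= smooth_order)
    xrd_error("bad_params", "smooth_window must be odd and > smooth_order")
  if (kalpha_ratio < 0 || kalpha_ratio > 1)
    xrd_error("bad_params", "kalpha_ratio must lie in [0, 1]")
  if (!(lambda2 > lambda1 && lambda1 > 0))
    xrd_error("bad_params", "need lambda2 > lambda1 > 0")
  structure(list(bg_degree = bg_degree, bg_max_iter = bg_max_iter,
                 bg_tol = bg_tol, smooth_window = smooth_window,
                 smooth_order = smooth_order, lambda1 = lambda1,
                 lambda2 = lambda2, kalpha_ratio = kalpha_ratio,
                 norm_mode = norm_mode),
            class = "xrd_preprocess_params")
}

#' Resample a pattern onto a uniform target grid
#'
#' Linear interpolation onto `seq(start, stop, by = step)`. The target may
#' extend past the source range by at most one source step; such edge points
#' take the nearest source value.
#'
#' @param p an [xrd_pattern()].
#' @param start,stop target range, degrees 2-theta.
#' @param step target step, degrees 2-theta.
#' @return resampled [xrd_pattern()].
#' @export
resample <- function(p, start, stop, step) {
  if (!is_xrd_pattern(p)) xrd_error("parse_error", "p is not an xrd_pattern")
  src <- range(p$two_theta)
  if (start < src[1] - p$meta$step || stop > src[2] + p$meta$step)
    xrd_error("range_error",
              "target grid extends beyond source by more than one step")
  grid <- seq(start, stop, by = step)
  y <- stats::approx(p$two_theta, p$intensity, xout = grid, rule = 2)$y
  pattern_with(xrd_pattern(grid, y, p$meta$wavelength_angstrom, p$meta$label),
               y)
}

#' Estimate the background of a diffractogram
#'
#' Iterative polynomial clipping: fit a least-squares polynomial of degree
#' `bg_degree`, replace every point lying above the fit by the fit, and
#' repeat until the background curve changes by less than `bg_tol` (relative)
#' or `bg_max_iter` is reached. Clipping removes the upward bias that peaks
#' exert on a single fit, so the result tracks the smooth baseline under
#' the peaks.
#'
#' @param p an [xrd_pattern()].
#' @param params an [preprocess_params()] object.
#' @return an [xrd_pattern()] holding the background curve.
#' @export
fit_background <- function(p, params = preprocess_params()) {
  if (!is_xrd_pattern(p)) xrd_error("parse_error", "p is not an xrd_pattern")
  n <- length(p$two_theta)
  deg <- params$bg_degree
  if (deg >= n / 4)
    xrd_error("bad_params", "bg_degree must be < length(p)/4")
  # centred/scaled abscissa for conditioning; design is fixed across iterations
  x <- 2 * (p$two_theta - min(p$two_theta)) / diff(range(p$two_theta)) - 1
  X <- outer(x, 0:deg, `^`)
  qrX <- qr(X)
  if (qrX$rank < deg + 1)
    xrd_error("degenerate_fit", "rank-deficient background design matrix")
  y <- p$intensity
  scale_ref <- max(abs(y), 1e-300)
  bg_old <- NULL
  for (it in seq_len(max(1, params$bg_max_iter))) {
    bg <- drop(X %*% qr.coef(qrX, y))
    y <- pmin(y, bg)
    if (!is.null(bg_old) &&
        max(abs(bg - bg_old)) / scale_ref < params$bg_tol) break
    bg_old <- bg
  }
  pattern_with(p, bg)
}

#' Subtract a background curve
#'
#' Pointwise `max(p - bg, 0)`: intensities are counts and cannot be negative.
#'
#' @param p,bg patterns on identical grids.
#' @return background-subtracted [xrd_pattern()].
#' @export
subtract_background <- function(p, bg) {
  if (!same_grid(p, bg)) xrd_error("grid_mismatch", "p and bg grids differ")
  pattern_with(p, pmax(p$intensity - bg$intensity, 0))
}

#' Savitzky-Golay smoothing
#'
#' Local polynomial filtering of the intensities: any input that is globally
#' a polynomial of degree at most `smooth_order` passes through unchanged
#' (edges included, where the local fit is evaluated off-centre).
#'
#' @param p an [xrd_pattern()].
#' @param params an [preprocess_params()] object.
#' @return smoothed [xrd_pattern()].
#' @export
smooth_pattern <- function(p, params = preprocess_params()) {
  if (!is_xrd_pattern(p)) xrd_error("parse_error", "p is not an xrd_pattern")
  if (params$smooth_window > length(p$two_theta))
    xrd_error("window_too_large", "smooth_window exceeds pattern length")
  y <- signal::sgolayfilt(p$intensity, p = params$smooth_order,
                          n = params$smooth_window)
  pattern_with(p, y)
}

#' Strip the K-alpha2 component (Rachinger method)
#'
#' An unfiltered Cu tube emits a doublet: every reflection at K-alpha1 angle
#' theta1 has a companion at theta2 = 2 asin((lambda2/lambda1) sin(theta1/2))
#' with `kalpha_ratio` times its intensity. Walking the grid in ascending
#' 2-theta, the already-stripped K-alpha1 intensity is interpolated at the
#' back-converted angle and `kalpha_ratio` times it is subtracted from the
#' observed intensity; results are clipped at zero. Angles whose K-alpha1
#' source falls below the grid are left untouched.
#'
#' @param p an [xrd_pattern()].
#' @param params an [preprocess_params()] object; the pattern wavelength must
#'   be consistent with `params$lambda1` (within 0.01 A).
#' @return stripped [xrd_pattern()].
#' @export
strip_kalpha2 <- function(p, params = preprocess_params()) {
  if (!is_xrd_pattern(p)) xrd_error("parse_error", "p is not an xrd_pattern")
  if (abs(p$meta$wavelength_angstrom - params$lambda1) > 0.01)
    xrd_warning("wavelength_mismatch",
                sprintf("pattern wavelength %.6g A far from lambda1 %.6g A",
                        p$meta$wavelength_angstrom, params$lambda1))
  r <- params$kalpha_ratio
  if (r == 0) return(p)
  tt <- p$two_theta
  n <- length(tt)
  step <- p$meta$step
  t0 <- tt[1]
  # K-alpha1 source angle for each grid point viewed as a K-alpha2 position
  theta1 <- convert_two_theta(tt, params$lambda2, params$lambda1)
  idx <- (theta1 - t0) / step          # fractional index, 0-based
  i0 <- floor(idx)
  w <- idx - i0                         # weight of the upper neighbour
  s <- p$intensity
  for (j in seq_len(n)) {
    lo <- i0[j] + 1                     # 1-based lower neighbour
    if (lo < 1) next                    # source below grid: nothing to strip
    hi <- lo + 1
    if (hi < j) {
      sub <- r * ((1 - w[j]) * s[lo] + w[j] * s[hi])
      s[j] <- max(0, s[j] - sub)
    } else {
      # source interval touches the current point: solve the implicit update
      # s[j] = I[j] - r * ((1-w) s[lo] + w s[j])
      s[j] <- max(0, (p$intensity[j] - r * (1 - w[j]) * s[lo]) /
                    (1 + r * w[j]))
    }
  }
  pattern_with(p, s)
}

#' Normalize a pattern
#'
#' `unit_max`: divide by the maximum intensity (peak value exactly 1) —
#' idempotent and invariant to uniform rescaling. `unit_area`: divide by
#' the rectangle-rule integral (sum times step).
#'
#' @param p an [xrd_pattern()].
#' @param params an [preprocess_params()] object (only `norm_mode` is used).
#' @return normalized [xrd_pattern()].
#' @export
normalize_pattern <- function(p, params = preprocess_params()) {
  if (!is_xrd_pattern(p)) xrd_error("parse_error", "p is not an xrd_pattern")
  m <- max(p$intensity)
  if (m <= 0) xrd_error("zero_pattern", "cannot normalize an all-zero pattern")
  y <- switch(params$norm_mode,
              unit_max = p$intensity / m,
              unit_area = p$intensity / (sum(p$intensity) * p$meta$step))
  pattern_with(p, y)
}

#' Run the full preprocessing pipeline
#'
#' Fixed stage order: background fit/subtraction, smoothing, K-alpha2
#' stripping, normalization. Each stage can be toggled off for ablation.
#'
#' @param p an [xrd_pattern()].
#' @param params an [preprocess_params()] object.
#' @param background,smooth,strip,normalize logical stage toggles.
#' @return preprocessed [xrd_pattern()].
#' @export
#' @examples
#' cfg <- sim_config(seed = 1)
#' raw <- render_pattern(xrd_phase("demo", c(12, 21.5), c(100, 60)), cfg)
#' pp <- preprocess(raw)
#' max(pp$intensity)  # 1 under unit-max normalization
preprocess <- function(p, params = preprocess_params(), background = TRUE,
                       smooth = TRUE, strip = TRUE, normalize = TRUE) {
  if (background) p <- subtract_background(p, fit_background(p, params))
  if (smooth) p <- smooth_pattern(p, params)
  if (strip) p <- strip_kalpha2(p, params)
  if (normalize) p <- normalize_pattern(p, params)
  p
}
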