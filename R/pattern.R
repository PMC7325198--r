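#' Construct a powder diffractogram
#'
#' A pattern is intensity (counts, arbitrary units) on a strictly increasing,
#' uniform grid of diffraction angles (degrees 2-theta). Uniformity is
#' required because downstream peak matching and the cross-correlation score
#' discretize integrals on a shared grid; patterns with grid jitter must be
#' put on a uniform grid explicitly with [resample()].
#'
#' @param two_theta numeric vector of angles, degrees 2-theta; strictly
#'   increasing, uniformly spaced (relative spacing deviation at most 1e-6),
#'   length at least 8.
#' @param intensity numeric vector of intensities, same length; all finite.
#' @param wavelength instrument wavelength in Angstrom (default Cu K-alpha
#'   weighted mean, 1.5418).
#' @param label free-text label carried through processing and reports.
#' @return an object of class `xrd_pattern`: a list with elements
#'   `two_theta`, `intensity` and `meta` (`wavelength_angstrom`, `label`,
#'   `step`).
#' @export
#' @examples
#' p <- xrd_pattern(seq(5, 6, by = 0.019), rexp(53), label = "demo")
#' print(p)
xrd_pattern <- function(two_theta, intensity, wavelength = 1.5418,
                        label = "") {
  two_theta <- as.numeric(two_theta)
  intensity <- as.numeric(intensity)
  if (length(two_theta) != length(intensity))
    xrd_error("length_mismatch", "two_theta and intensity differ in length")
  if (length(two_theta) < 8)
    xrd_error("too_few_points",
              sprintf("pattern needs >= 8 points, got %d", length(two_theta)))
  if (!all(is.finite(two_theta)) || !all(is.finite(intensity)))
    xrd_error("parse_error", "non-finite values in pattern")
  d <- diff(two_theta)
  if (any(d <= 0))
    xrd_error("non_monotone_grid", "two_theta must be strictly increasing")
  step <- stats::median(d)
  if (max(abs(d - step)) / step > 1e-6)
    xrd_error("nonuniform_grid",
              "grid spacing non-uniform beyond 1e-6 relative; resample first")
  structure(
    list(two_theta = two_theta, intensity = intensity,
         meta = list(wavelength_angstrom = wavelength, label = label,
                     step = step)),
    class = "xrd_pattern"
  )
}

is_xrd_pattern <- function(x) inherits(x, "xrd_pattern")

# Same grid: equal length and pointwise agreement well below one step.
same_grid <- function(a, b) {
  length(a$two_theta) == length(b$two_theta) &&
    max(abs(a$two_theta - b$two_theta)) < 1e-6 * a$meta$step
}

# Rebuild a pattern with new intensities, keeping grid and metadata.
pattern_with <- function(p, intensity, label = p$meta$label) {
  structure(
    list(two_theta = p$two_theta, intensity = as.numeric(intensity),
         meta = list(wavelength_angstrom = p$meta$wavelength_angstrom,
                     label = label, step = p$meta$step)),
    class = "xrd_pattern"
  )
}

#' @export
print.xrd_pattern <- function(x, ...) {
  cat(sprintf(
    "<xrd_pattern> %s\n  %d points, %.4g-%.4g deg 2theta (step %.4g), lambda %.6g A\n  intensity range [%.4g, %.4g]\n",
    if (nzchar(x$meta$label)) x$meta$label else "(unlabelled)",
    length(x$two_theta), min(x$two_theta), max(x$two_theta), x$meta$step,
    x$meta$wavelength_angstrom, min(x$intensity), max(x$intensity)))
  invisible(x)
}

#' @export
plot.xrd_pattern <- function(x, ..., type = "l",
                             xlab = expression(2 * theta ~ (degrees)),
                             ylab = "Intensity (a.u.)",
                             main = x$meta$label) {
  graphics::plot(x$two_theta, x$intensity, type = type, xlab = xlab,
                 ylab = ylab, main = main, ...)
  invisible(x)
}

#' @export
as.data.frame.xrd_pattern <- function(x, ...) {
  data.frame(two_theta = x$two_theta, intensity = x$intensity)
}

#' Construct a reference phase (peak list)
#'
#' A phase is the diffraction fingerprint of one substance: reflection
#' positions (degrees 2-theta at a stated reference wavelength) with relative
#' intensities. Relative intensities are rescaled so the strongest reflection
#' is 100, the convention used by powder-diffraction reference cards.
#'
#' @param name substance name.
#' @param positions reflection positions, degrees 2-theta, each in (0, 180).
#' @param rel_intensity positive relative intensities, same length.
#' @param ref_wavelength wavelength (Angstrom) at which positions are
#'   tabulated; default 1.5418 (Cu K-alpha).
#' @return an object of class `xrd_phase`: list with `name`, `reflections`
#'   (data.frame `position`, `rel_intensity`, sorted by position) and
#'   `ref_wavelength_angstrom`.
#' @export
xrd_phase <- function(name, positions, rel_intensity,
                      ref_wavelength = 1.5418) {
  positions <- as.numeric(positions)
  rel_intensity <- as.numeric(rel_intensity)
  if (length(positions) != length(rel_intensity))
    xrd_error("length_mismatch", "positions and rel_intensity differ in length")
  if (any(positions <= 0 | positions >= 180))
    xrd_error("parse_error", "reflection positions must lie in (0, 180)")
  if (any(!is.finite(rel_intensity) | rel_intensity <= 0))
    xrd_error("parse_error", "relative intensities must be finite and > 0")
  o <- order(positions)
  rel <- if (length(rel_intensity)) 100 * rel_intensity[o] / max(rel_intensity)
         else numeric(0)
  structure(
    list(name = as.character(name),
         reflections = data.frame(
           position = positions[o],
           rel_intensity = rel),
         ref_wavelength_angstrom = ref_wavelength),
    class = "xrd_phase"
  )
}

#' @export
print.xrd_phase <- function(x, ...) {
  if (nrow(x$reflections) == 0) {
    cat(sprintf("<xrd_phase> %s: no reflections\n", x$name))
    return(invisible(x))
  }
  cat(sprintf("<xrd_phase> %s: %d reflections at lambda %.6g A, strongest at %.3f deg 2theta\n",
              x$name, nrow(x$reflections), x$ref_wavelength_angstrom,
              x$reflections$position[which.max(x$reflections$rel_intensity)]))
  invisible(x)
}
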