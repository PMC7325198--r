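# Small shared helpers.

#' Convert diffraction angles between wavelengths
#'
#' Moves peak positions from one X-ray wavelength to another via Bragg's law,
#' \eqn{\lambda = 2 d \sin\theta}: the lattice spacing d is fixed, so
#' \eqn{\sin\theta_{new} = (\lambda_{new}/\lambda_{old}) \sin\theta_{old}}.
#' Angles whose converted sine would exceed 1 are clamped to 180 degrees.
#'
#' @param two_theta numeric vector of diffraction angles, degrees 2-theta.
#' @param from_wavelength wavelength at which `two_theta` is tabulated, in
#'   Angstrom.
#' @param to_wavelength target wavelength, Angstrom.
#' @return numeric vector of converted angles, degrees 2-theta.
#' @export
#' @examples
#' convert_two_theta(30, 1.540562, 1.544398)
convert_two_theta <- function(two_theta, from_wavelength, to_wavelength) {
  stopifnot(from_wavelength > 0, to_wavelength > 0)
  s <- (to_wavelength / from_wavelength) * sin(two_theta * pi / 360)
  2 * asin(pmin(1, s)) * 180 / pi
}

# Evaluate a polynomial with ascending coefficients c0 + c1*x + c2*x^2 + ...
polyval_asc <- function(coeffs, x) {
  y <- rep(0, length(x))
  for (k in rev(seq_along(coeffs))) y <- y * x + coeffs[[k]]
  y
}

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
# seed = NULL means "use the ambient RNG stream".
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (!exists(".Random.seed", globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  eval.parent(substitute(expr))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
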