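# Cross-correlation score (CCS) for quantitative diffractogram comparison.
#
# With f'(theta) the normalized standard and g'(theta) the normalized sample,
# the patterns are first squared, f = f'^2 and g = g'^2, to accentuate peaks
# and attenuate background noise and minor pollutants. The score is
#
#   CCS_fg = Int C_fg(tau) dtau / Int C_ff(tau) dtau,
#
# with C_fg the cross-correlation and C_ff the auto-correlation of the
# squared patterns. Integrals are discretized as rectangle sums on the shared
# grid; the grid step cancels in the ratio.
#
# Taken literally over all lags the numerator factorizes,
# sum_tau C_fg = step * (sum f)(sum g), so the full-lag score collapses to
# (sum g)/(sum f) and carries no peak-position information. The windowed
# mode, which restricts |tau| <= max_lag, restores position sensitivity
# while still absorbing small 2-theta misalignments; it is the recommended
# mode for identification. Both modes are provided.

#' Square a normalized pattern
#'
#' Pointwise square; applied to normalized diffractograms before
#' cross-correlation to accentuate peaks over background.
#'
#' @param p an [xrd_pattern()].
#' @return squared [xrd_pattern()] on the same grid.
#' @export
square_pattern <- function(p) {
  if (!is_xrd_pattern(p)) xrd_error("parse_error", "p is not an xrd_pattern")
  pattern_with(p, p$intensity^2)
}

#' Discrete cross-correlation of two patterns
#'
#' Computes `C[k] = step * sum_i f[i] g[i + k]` for every lag
#' `k = -(N-1), ..., N-1`, with values outside the support treated as zero
#' (FFT-based, exact to round-off).
#'
#' @param f,g patterns on identical grids (standard first).
#' @return an object of class `xrd_corr`: list with `lags` (degrees 2-theta,
#'   symmetric about 0) and `values` (intensity^2 x degrees).
#' @export
correlate <- function(f, g) {
  if (!is_xrd_pattern(f) || !is_xrd_pattern(g))
    xrd_error("parse_error", "inputs must be xrd_pattern")
  if (!same_grid(f, g)) xrd_error("grid_mismatch", "f and g grids differ")
  n <- length(f$intensity)
  step <- f$meta$step
  # convolve(g, f, "open") (conj = TRUE) is the correlation
  # sum_i f[i] g[i+k] in ascending lag order
  z <- stats::convolve(g$intensity, f$intensity, type = "open")
  structure(
    list(lags = step * seq(-(n - 1), n - 1), values = step * z),
    class = "xrd_corr"
  )
}

#' @export
print.xrd_corr <- function(x, ...) {
  cat(sprintf("<xrd_corr> %d lags in [%.4g, %.4g] deg 2theta, peak %.4g at %.4g\n",
              length(x$lags), min(x$lags), max(x$lags),
              max(x$values), x$lags[which.max(x$values)]))
  invisible(x)
}

# Sum of step * C_fg over lags |k| <= kmax, computed by direct shifted sums
# (no full correlation needed). Returns step^2 * sum_{|k|<=kmax} sum_i f_i g_{i+k}.
windowed_corr_sum <- function(f, g, step, kmax) {
  n <- length(f)
  total <- sum(f * g)
  if (kmax > 0) for (k in seq_len(min(kmax, n - 1))) {
    total <- total + sum(f[1:(n - k)] * g[(1 + k):n]) +
      sum(f[(1 + k):n] * g[1:(n - k)])
  }
  step^2 * total
}

#' Cross-correlation score of a sample against a standard
#'
#' Squares both (already normalized) patterns, cross-correlates them, and
#' returns the ratio of the integrated cross-correlation to the integrated
#' auto-correlation of the standard. `mode = "full"` integrates over all
#' lags (the literal definition; position-insensitive, see Details in the
#' package vignette); `mode = "windowed"` integrates over `|tau| <= max_lag`
#' and is the recommended identification score. A sample identical to the
#' standard scores exactly 1 in either mode.
#'
#' @param standard,sample preprocessed, normalized patterns on a common grid.
#' @param mode `"windowed"` (default) or `"full"`.
#' @param max_lag lag window half-width, degrees 2-theta (default 0.5);
#'   ignored in full mode.
#' @param square square the patterns first (default `TRUE`; set `FALSE` if
#'   inputs are already squared).
#' @return an object of class `xrd_ccs`: `score`, `mode`, `max_lag`, `step`,
#'   `standard_label`, `sample_label`.
#' @export
#' @examples
#' cfg <- sim_config(noise_scale = 0, bg_coeffs = 0)
#' ph <- xrd_phase("demo", c(12, 21.5), c(100, 60))
#' p <- normalize_pattern(render_pattern(ph, cfg))
#' ccs(p, p)$score  # exactly 1
ccs <- function(standard, sample, mode = c("windowed", "full"), max_lag = 0.5,
                square = TRUE) {
  mode <- match.arg(mode)
  if (!is_xrd_pattern(standard) || !is_xrd_pattern(sample))
    xrd_error("parse_error", "inputs must be xrd_pattern")
  if (!same_grid(standard, sample))
    xrd_error("grid_mismatch", "standard and sample grids differ")
  if (mode == "windowed" && max_lag <= 0)
    xrd_error("bad_params", "max_lag must be > 0 in windowed mode")
  f <- if (square) standard$intensity^2 else standard$intensity
  g <- if (square) sample$intensity^2 else sample$intensity
  step <- standard$meta$step
  if (mode == "full") {
    fp <- pattern_with(standard, f)
    num <- sum(correlate(fp, pattern_with(sample, g))$values) * step
    den <- sum(correlate(fp, fp)$values) * step
  } else {
    kmax <- floor(max_lag / step + 1e-9)
    num <- windowed_corr_sum(f, g, step, kmax)
    den <- windowed_corr_sum(f, f, step, kmax)
  }
  if (den == 0)
    xrd_error("zero_denominator", "standard pattern is identically zero")
  structure(
    list(score = num / den, mode = mode,
         max_lag = if (mode == "full") Inf else max_lag, step = step,
         standard_label = standard$meta$label,
         sample_label = sample$meta$label),
    class = "xrd_ccs"
  )
}

#' @export
print.xrd_ccs <- function(x, ...) {
  cat(sprintf("<xrd_ccs> %s vs %s: score %.4f (%s mode%s)\n",
              if (nzchar(x$standard_label)) x$standard_label else "standard",
              if (nzchar(x$sample_label)) x$sample_label else "sample",
              x$score, x$mode,
              if (is.finite(x$max_lag))
                sprintf(", max_lag %.3g deg", x$max_lag) else ""))
  invisible(x)
}

#' Pairwise cross-correlation score matrix
#'
#' Entry (i, j) is the score of pattern j (sample) against pattern i
#' (standard). The diagonal is exactly 1. The matrix is generally
#' asymmetric: the denominator is the standard's auto-correlation, which
#' depends on the row.
#'
#' @param patterns list of preprocessed, normalized patterns on a common
#'   grid.
#' @param mode,max_lag see [ccs()].
#' @return a numeric matrix of class `xrd_ccs_matrix` with pattern labels as
#'   dimnames and attributes `mode` and `max_lag`.
#' @export
ccs_matrix <- function(patterns, mode = c("windowed", "full"), max_lag = 0.5) {
  mode <- match.arg(mode)
  n <- length(patterns)
  if (n == 0) xrd_error("bad_params", "no patterns given")
  for (p in patterns) {
    if (!is_xrd_pattern(p)) xrd_error("parse_error", "inputs must be xrd_pattern")
    if (!same_grid(patterns[[1]], p))
      xrd_error("grid_mismatch", "patterns must share a common grid")
  }
  step <- patterns[[1]]$meta$step
  sq <- lapply(patterns, function(p) p$intensity^2)
  kmax <- floor(max_lag / step + 1e-9)
  corr_sum <- function(a, b) {
    if (mode == "full") {
      pa <- pattern_with(patterns[[1]], a)
      sum(correlate(pa, pattern_with(patterns[[1]], b))$values) * step
    } else windowed_corr_sum(a, b, step, kmax)
  }
  den <- vapply(sq, function(f) corr_sum(f, f), numeric(1))
  if (any(den == 0))
    xrd_error("zero_denominator", "a pattern is identically zero")
  m <- matrix(1, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    m[i, j] <- corr_sum(sq[[i]], sq[[j]]) / den[i]
  }
  labels <- vapply(patterns, function(p) p$meta$label, character(1))
  labels[!nzchar(labels)] <- sprintf("pattern_%d", which(!nzchar(labels)))
  dimnames(m) <- list(standard = labels, sample = labels)
  structure(m, class = c("xrd_ccs_matrix", "matrix", "array"),
            mode_used = mode, max_lag = if (mode == "full") Inf else max_lag)
}

#' @export
print.xrd_ccs_matrix <- function(x, ...) {
  cat(sprintf("<xrd_ccs_matrix> %d x %d, %s mode%s\n", nrow(x), ncol(x),
              attr(x, "mode_used"),
              if (is.finite(attr(x, "max_lag")))
                sprintf(", max_lag %.3g deg", attr(x, "max_lag")) else ""))
  print(round(unclass(x), 4))
  invisible(x)
}

#' @export
plot.xrd_ccs_matrix <- function(x, ..., main = "Cross-correlation score") {
  n <- nrow(x)
  m <- unclass(x)
  graphics::image(seq_len(n), seq_len(n), t(m[n:1, , drop = FALSE]),
                  axes = FALSE, xlab = "sample", ylab = "standard",
                  main = main, ...)
  graphics::axis(1, at = seq_len(n), labels = colnames(x), las = 2,
                 cex.axis = 0.7)
  graphics::axis(2, at = seq_len(n), labels = rev(rownames(x)), las = 2,
                 cex.axis = 0.7)
  graphics::box()
  invisible(x)
}
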