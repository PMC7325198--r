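# Peak detection and position-based phase identification. Identification
# keys on peak positions, not relative intensities: crystal habit and
# grinding change intensities but not positions, so position agreement is
# the forensic fingerprint.

#' Detect diffraction peaks
#'
#' Finds local maxima of a preprocessed (smoothed, normalized) pattern that
#' exceed both a height and a prominence threshold, each expressed as a
#' fraction of the pattern maximum. The apex position and height are refined
#' by a 3-point parabola through the apex and its neighbours, so positions
#' are not quantized to the grid.
#'
#' @param p a preprocessed [xrd_pattern()].
#' @param min_rel_height minimum peak height, fraction of the pattern
#'   maximum (default 0.01).
#' @param min_rel_prominence minimum prominence (height above the higher of
#'   the two flanking valleys), fraction of the pattern maximum (default
#'   0.005).
#' @return an object of class `xrd_peaks`: list with `peaks` (data.frame
#'   `position`, `height`, `prominence`, sorted by position) and
#'   `source_label`. A flat pattern yields an empty peak list.
#' @export
detect_peaks <- function(p, min_rel_height = 0.01,
                         min_rel_prominence = 0.005) {
  if (!is_xrd_pattern(p)) xrd_error("parse_error", "p is not an xrd_pattern")
  y <- p$intensity
  n <- length(y)
  ymax <- max(y)
  cand <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] > y[3:n]) + 1L
  keep_pos <- numeric(0); keep_h <- numeric(0); keep_prom <- numeric(0)
  for (i in cand) {
    h <- y[i]
    if (h < min_rel_height * ymax) next
    # prominence: on each side, the minimum before reaching a higher point
    left <- if (i > 1) y[seq_len(i - 1)] else h
    hl <- which(left > h)
    lmin <- min(left[if (length(hl)) (max(hl) + 1):(i - 1) else seq_len(i - 1)])
    right <- if (i < n) y[(i + 1):n] else h
    hr <- which(right > h)
    rmin <- min(right[seq_len(if (length(hr)) min(hr) - 1 else length(right))])
    prom <- h - max(lmin, rmin)
    if (prom < min_rel_prominence * ymax) next
    # parabolic apex refinement
    y1 <- y[i - 1]; y2 <- y[i]; y3 <- y[i + 1]
    denom <- y1 - 2 * y2 + y3
    delta <- if (denom != 0) 0.5 * (y1 - y3) / denom else 0
    delta <- max(-0.5, min(0.5, delta))
    keep_pos <- c(keep_pos, p$two_theta[i] + delta * p$meta$step)
    keep_h <- c(keep_h, y2 - 0.25 * (y1 - y3) * delta)
    keep_prom <- c(keep_prom, prom)
  }
  xrd_peaklist(keep_pos, keep_h, keep_prom, p$meta$label)
}

xrd_peaklist <- function(position, height, prominence, source_label = "") {
  o <- order(position)
  structure(
    list(peaks = data.frame(position = position[o], height = height[o],
                            prominence = prominence[o]),
         source_label = source_label),
    class = "xrd_peaks"
  )
}

#' @export
print.xrd_peaks <- function(x, ...) {
  cat(sprintf("<xrd_peaks> %s: %d peaks\n",
              if (nzchar(x$source_label)) x$source_label else "(unlabelled)",
              nrow(x$peaks)))
  if (nrow(x$peaks)) print(format(x$peaks, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Match sample peaks against a standard's peaks
#'
#' Greedy closest-first pairing: all (standard, sample) position pairs within
#' `tolerance` are ranked by absolute position difference (ties broken toward
#' lower angle) and paired off, each peak used at most once. Intensities play
#' no role — an exact match of relative intensities is not required for
#' identification.
#'
#' @param sample,standard [detect_peaks()] results (or `xrd_peaks` built from
#'   a reference card).
#' @param tolerance maximum |position difference| for a pair, degrees 2-theta
#'   (default 0.10, about five steps of a 0.019-degree grid).
#' @return an object of class `xrd_match`: `tolerance`, `matched`
#'   (data.frame `standard_position`, `sample_position`, `delta`),
#'   `fraction_matched` (matched standard peaks / total standard peaks),
#'   `extra_sample_peaks` (positions of unpaired sample peaks, with their
#'   heights in `extra_sample_heights`) and `candidate` (standard label).
#' @export
match_peaks <- function(sample, standard, tolerance = 0.10) {
  if (!inherits(sample, "xrd_peaks") || !inherits(standard, "xrd_peaks"))
    xrd_error("parse_error", "sample and standard must be xrd_peaks")
  if (nrow(standard$peaks) == 0)
    xrd_error("empty_standard", "standard peak list is empty")
  if (tolerance <= 0) xrd_error("bad_params", "tolerance must be > 0")
  sp <- standard$peaks$position
  qp <- sample$peaks$position
  pairs <- expand.grid(is = seq_along(sp), iq = seq_along(qp))
  pairs$delta <- qp[pairs$iq] - sp[pairs$is]
  pairs <- pairs[abs(pairs$delta) <= tolerance, , drop = FALSE]
  pairs <- pairs[order(abs(pairs$delta), sp[pairs$is], qp[pairs$iq]), ,
                 drop = FALSE]
  used_s <- logical(length(sp)); used_q <- logical(length(qp))
  keep <- integer(0)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$is[k]; j <- pairs$iq[k]
    if (used_s[i] || used_q[j]) next
    used_s[i] <- TRUE; used_q[j] <- TRUE
    keep <- c(keep, k)
  }
  m <- pairs[keep, , drop = FALSE]
  m <- m[order(sp[m$is]), , drop = FALSE]
  structure(
    list(tolerance = tolerance,
         matched = data.frame(standard_position = sp[m$is],
                              sample_position = qp[m$iq],
                              delta = m$delta),
         fraction_matched = sum(used_s) / length(sp),
         extra_sample_peaks = qp[!used_q],
         extra_sample_heights = sample$peaks$height[!used_q],
         candidate = standard$source_label),
    class = "xrd_match"
  )
}

# Extras worth reporting: relatively intensive unmatched sample peaks.
# Weak unmatched ripples (counting noise) stay in the report object but are
# not printed.
notable_extras <- function(x, min_height = 0.05) {
  h <- x$extra_sample_heights
  if (is.null(h) || !length(h)) return(numeric(0))
  x$extra_sample_peaks[h >= min_height * max(c(h, 1))]
}

#' @export
print.xrd_match <- function(x, ...) {
  cat(sprintf(
    "<xrd_match> candidate '%s': %.0f%% of standard peaks matched (tol %.3g deg)\n",
    x$candidate, 100 * x$fraction_matched, x$tolerance))
  extras <- notable_extras(x)
  if (length(extras))
    cat("  intensive extra sample peaks (possible adulterants):",
        paste(sprintf("%.2f", extras), collapse = ", "), "\n")
  invisible(x)
}

# Ideal peak list of a phase at a target wavelength.
phase_peaklist <- function(phase, wavelength) {
  pos <- convert_two_theta(phase$reflections$position,
                           phase$ref_wavelength_angstrom, wavelength)
  h <- phase$reflections$rel_intensity / 100
  xrd_peaklist(pos, h, h, phase$name)
}

#' Identify a sample against a phase library
#'
#' Full identification pipeline: preprocess the sample, detect its peaks,
#' match them against the ideal peak list of every library phase (positions
#' converted to the sample's wavelength by Bragg's law when wavelengths
#' differ), and rank candidates by the fraction of standard peaks matched.
#' Candidates tied on that fraction are ordered by a lag-windowed
#' cross-correlation score between the preprocessed sample and a noise-free
#' rendering of the phase — not by relative intensities, which vary with
#' crystal habit and grinding. Unpaired sample peaks are surfaced as
#' possible-adulterant flags.
#'
#' @param sample an [xrd_pattern()], raw or already preprocessed.
#' @param library a list of [xrd_phase()] objects.
#' @param params [preprocess_params()] used when `preprocess = TRUE` and for
#'   rendering tie-break patterns.
#' @param tolerance position-matching tolerance, degrees 2-theta.
#' @param min_rel_height,min_rel_prominence peak-detection thresholds, see
#'   [detect_peaks()].
#' @param max_lag lag window of the tie-break score, degrees 2-theta.
#' @param fwhm peak width used when rendering tie-break patterns.
#' @param preprocess run the preprocessing pipeline on `sample` first.
#' @return an object of class `xrd_identification`: a list of `xrd_match`
#'   reports in rank order, with attributes recording the settings.
#' @export
identify_phases <- function(sample, library, params = preprocess_params(),
                            tolerance = 0.10, min_rel_height = 0.01,
                            min_rel_prominence = 0.005, max_lag = 0.5,
                            fwhm = 0.1, preprocess = TRUE) {
  if (length(library) == 0) xrd_error("empty_library", "phase library is empty")
  sp <- if (preprocess) preprocess(sample, params) else sample
  pk <- detect_peaks(sp, min_rel_height, min_rel_prominence)
  wl <- sp$meta$wavelength_angstrom
  reports <- lapply(library, function(ph)
    match_peaks(pk, phase_peaklist(ph, wl), tolerance))
  frac <- vapply(reports, function(r) r$fraction_matched, numeric(1))

  # tie-break by windowed CCS against a clean rendering, computed lazily
  tie_ccs <- rep(NA_real_, length(reports))
  cfg <- sim_config(start = min(sp$two_theta), stop = max(sp$two_theta),
                    step = sp$meta$step, fwhm = fwhm, doublet = FALSE,
                    lambda1 = wl, bg_coeffs = 0, noise_scale = 0,
                    intensity_sigma = 0)
  for (f in unique(frac[duplicated(frac)])) {
    idx <- which(frac == f)
    for (i in idx) {
      ideal <- suppressWarnings(render_pattern(library[[i]], cfg))
      if (max(ideal$intensity) <= 0) { tie_ccs[i] <- 0; next }
      ideal <- normalize_pattern(ideal, params)
      tie_ccs[i] <- ccs(ideal, sp, mode = "windowed", max_lag = max_lag)$score
    }
  }
  o <- order(-frac, -ifelse(is.na(tie_ccs), -Inf, tie_ccs))
  out <- reports[o]
  for (k in seq_along(out)) out[[k]]$tiebreak_ccs <- tie_ccs[o][k]
  structure(out, class = "xrd_identification", tolerance = tolerance,
            max_lag = max_lag, sample_label = sp$meta$label)
}

#' @export
print.xrd_identification <- function(x, ...) {
  cat(sprintf("<xrd_identification> sample '%s' vs %d phases (tol %.3g deg)\n",
              attr(x, "sample_label"), length(x), attr(x, "tolerance")))
  df <- data.frame(
    rank = seq_along(x),
    candidate = vapply(x, function(r) r$candidate, character(1)),
    fraction_matched = vapply(x, function(r) r$fraction_matched, numeric(1)),
    tiebreak_ccs = vapply(x, function(r) r$tiebreak_ccs %||% NA_real_,
                          numeric(1)),
    extra_peaks = vapply(x, function(r) length(r$extra_sample_peaks),
                         integer(1)))
  print(format(df, digits = 4), row.names = FALSE)
  extras <- notable_extras(x[[1]])
  if (length(extras))
    cat("possible adulterant peaks (top candidate, intensive extras):",
        paste(sprintf("%.2f", extras), collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a match report
#'
#' @param x an `xrd_match` or `xrd_identification`.
#' @param path destination file; `.json` extension selects JSON, anything
#'   else delimited text.
#' @return `path`, invisibly.
#' @export
write_match_report <- function(x, path) {
  to_list <- function(r) list(
    candidate = r$candidate, tolerance = r$tolerance,
    fraction_matched = r$fraction_matched,
    matched = r$matched, extra_sample_peaks = r$extra_sample_peaks,
    tiebreak_ccs = r$tiebreak_ccs %||% NA_real_)
  reports <- if (inherits(x, "xrd_identification")) lapply(x, to_list)
             else list(to_list(x))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(reports, path, auto_unbox = TRUE, digits = NA)
  } else {
    df <- do.call(rbind, lapply(seq_along(reports), function(k) {
      r <- reports[[k]]
      data.frame(rank = k, candidate = r$candidate,
                 fraction_matched = r$fraction_matched,
                 tiebreak_ccs = r$tiebreak_ccs,
                 n_extra_peaks = length(r$extra_sample_peaks),
                 extra_peaks = paste(sprintf("%.3f", r$extra_sample_peaks),
                                     collapse = ";"))
    }))
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
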