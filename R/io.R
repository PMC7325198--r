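# Plain-text diffractogram and phase-library I/O.
#
# XY/ASC dialect: one "angle intensity" pair per line, whitespace- or
# comma-separated; optional leading '#' comment lines may carry
# "key: value" metadata (label, wavelength_angstrom).

#' Read a two-column XY/ASC diffractogram
#'
#' Tolerant reader for the plain-text format exported by most diffractometer
#' software: two (or more) numeric columns, whitespace- or comma-separated,
#' optionally preceded by header/comment lines. Only the first two columns
#' (angle, intensity) are used.
#'
#' @param path file to read.
#' @param allow_headers if `TRUE` (default), leading non-numeric lines and
#'   `#` comments are skipped; `# key: value` comments populate pattern
#'   metadata. If `FALSE`, any non-numeric line is an error.
#' @return an [xrd_pattern()].
#' @export
read_xy <- function(path, allow_headers = TRUE) {
  if (!file.exists(path))
    xrd_error("io_failure", sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]

  label <- ""
  wavelength <- 1.5418
  parse_row <- function(ln) {
    suppressWarnings(as.numeric(strsplit(ln, "[,;[:space:]]+")[[1]]))
  }

  rows <- vector("list", length(lines))
  n <- 0L
  seen_data <- FALSE
  for (ln in lines) {
    if (startsWith(ln, "#")) {
      if (!allow_headers)
        xrd_error("parse_error", "comment line found with allow_headers = FALSE")
      body <- trimws(sub("^#+", "", ln))
      m <- regmatches(body, regexec("^([A-Za-z_]+)\\s*:\\s*(.*)$", body))[[1]]
      if (length(m) == 3) {
        key <- tolower(m[2])
        if (key == "label") label <- m[3]
        if (key == "wavelength_angstrom") {
          w <- suppressWarnings(as.numeric(m[3]))
          if (is.finite(w)) wavelength <- w
        }
      }
      next
    }
    vals <- parse_row(ln)
    if (length(vals) < 2 || anyNA(vals[1:2])) {
      if (!seen_data && allow_headers) next  # leading header line
      xrd_error("parse_error", sprintf("malformed numeric row: '%s'", ln))
    }
    seen_data <- TRUE
    n <- n + 1L
    rows[[n]] <- vals[1:2]
  }
  if (n < 8)
    xrd_error("too_few_points",
              sprintf("need >= 8 data rows, found %d in %s", n, path))
  m <- do.call(rbind, rows[seq_len(n)])
  xrd_pattern(m[, 1], m[, 2], wavelength = wavelength, label = label)
}

#' Write a diffractogram as a two-column XY file
#'
#' Values are written with 6 significant digits (below instrument precision,
#' above the 1e-6 relative round-trip tolerance); label and wavelength go
#' into `#` header comments so that [read_xy()] reproduces the pattern.
#'
#' @param p an [xrd_pattern()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_xy <- function(p, path) {
  if (!is_xrd_pattern(p)) xrd_error("parse_error", "p is not an xrd_pattern")
  header <- c(
    sprintf("# label: %s", p$meta$label),
    sprintf("# wavelength_angstrom: %.8g", p$meta$wavelength_angstrom)
  )
  body <- sprintf("%.6g %.6g", p$two_theta, p$intensity)
  ok <- tryCatch({
    writeLines(c(header, body), path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) xrd_error("io_failure", sprintf("cannot write: %s", path))
  invisible(path)
}

#' Read a phase library
#'
#' The library is delimited text (comma or whitespace) with a header row and
#' columns `phase_name`, `position_2theta`, `rel_intensity`, plus an optional
#' `wavelength_angstrom` column (per phase; default 1.5418). Relative
#' intensities are rescaled per phase so the strongest reflection is 100.
#'
#' @param path file to read.
#' @return a named list of [xrd_phase()] objects, in order of first
#'   appearance.
#' @export
read_phase_library <- function(path) {
  if (!file.exists(path))
    xrd_error("io_failure", sprintf("file not found: %s", path))
  first <- readLines(path, n = 50, warn = FALSE)
  first <- first[nzchar(trimws(first)) & !startsWith(trimws(first), "#")]
  if (length(first) == 0) xrd_error("empty_library", "no phases in library")
  sep <- if (grepl(",", first[1], fixed = TRUE)) "," else ""
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                      strip.white = TRUE, stringsAsFactors = FALSE),
    error = function(e) xrd_error("parse_error", conditionMessage(e)))
  need <- c("phase_name", "position_2theta", "rel_intensity")
  if (!all(need %in% names(df)))
    xrd_error("parse_error",
              paste("library must have columns:", paste(need, collapse = ", ")))
  if (nrow(df) == 0) xrd_error("empty_library", "no phases in library")
  if (!is.numeric(df$position_2theta) || !is.numeric(df$rel_intensity))
    xrd_error("parse_error", "non-numeric reflection data in library")
  phases <- list()
  for (nm in unique(df$phase_name)) {
    sub <- df[df$phase_name == nm, , drop = FALSE]
    wl <- if ("wavelength_angstrom" %in% names(sub))
      sub$wavelength_angstrom[1] else 1.5418
    phases[[nm]] <- xrd_phase(nm, sub$position_2theta, sub$rel_intensity,
                              ref_wavelength = wl)
  }
  phases
}

#' Write a phase library
#'
#' @param phases list of [xrd_phase()] objects.
#' @param path destination CSV file.
#' @return `path`, invisibly.
#' @export
write_phase_library <- function(phases, path) {
  if (length(phases) == 0) xrd_error("empty_library", "no phases to write")
  rows <- do.call(rbind, lapply(phases, function(ph) {
    data.frame(phase_name = ph$name,
               position_2theta = ph$reflections$position,
               rel_intensity = ph$reflections$rel_intensity,
               wavelength_angstrom = ph$ref_wavelength_angstrom)
  }))
  ok <- tryCatch({
    utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) xrd_error("io_failure", sprintf("cannot write: %s", path))
  invisible(path)
}
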