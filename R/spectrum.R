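#' Construct a spectrum
#'
#' A spectrum is a strictly ascending wavenumber axis (cm^-1) paired with
#' intensities in arbitrary units, plus a free-text label (typically a polymer
#' or compound name). Files arriving with a descending axis are sorted on
#' construction, so the ascending invariant always holds.
#'
#' @param wavenumbers Numeric vector, finite, no duplicates.
#' @param intensities Numeric vector of the same length (>= 2), finite.
#' @param label Free-text identity; defaults to `"spectrum"`.
#' @param degenerate Logical flag set by [normalize_minmax()] when a flat
#'   spectrum was normalized to zeros.
#' @return An object of class `specmend_spectrum`.
#' @export
new_spectrum <- function(wavenumbers, intensities, label = "spectrum",
                         degenerate = FALSE) {
  wavenumbers <- as.numeric(wavenumbers)
  intensities <- as.numeric(intensities)
  if (length(wavenumbers) != length(intensities)) {
    stop("wavenumbers and intensities must have equal length", call. = FALSE)
  }
  if (length(wavenumbers) < 2L) {
    stop("a spectrum needs at least 2 points", call. = FALSE)
  }
  if (!all(is.finite(wavenumbers)) || !all(is.finite(intensities))) {
    stop("wavenumbers and intensities must be finite", call. = FALSE)
  }
  if (is.unsorted(wavenumbers)) {
    ord <- order(wavenumbers)
    wavenumbers <- wavenumbers[ord]
    intensities <- intensities[ord]
  }
  if (any(diff(wavenumbers) <= 0)) {
    stop("wavenumbers must be strictly increasing (no duplicates)",
         call. = FALSE)
  }
  structure(
    list(wavenumbers = wavenumbers, intensities = intensities,
         label = as.character(label)[1L], degenerate = isTRUE(degenerate)),
    class = "specmend_spectrum"
  )
}

#' @export
print.specmend_spectrum <- function(x, ...) {
  cat(sprintf("<spectrum '%s': %d points, %.1f-%.1f cm^-1%s>\n",
              x$label, length(x$wavenumbers),
              min(x$wavenumbers), max(x$wavenumbers),
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' @export
length.specmend_spectrum <- function(x) length(x$wavenumbers)

# Split a delimited line into fields. `dialect` is one of "auto", ",", ";",
# "\t", "whitespace".
split_fields <- function(line, dialect) {
  if (dialect == "auto") {
    dialect <- if (grepl(";", line, fixed = TRUE)) ";"
      else if (grepl(",", line, fixed = TRUE)) ","
      else if (grepl("\t", line, fixed = TRUE)) "\t"
      else "whitespace"
  }
  if (dialect == "whitespace") {
    strsplit(trimws(line), "[[:space:]]+")[[1L]]
  } else {
    trimws(strsplit(line, dialect, fixed = TRUE)[[1L]])
  }
}

#' Read a two-column spectrum file
#'
#' Parses delimited text with one wavenumber/intensity pair per row. The
#' delimiter is auto-detected among comma, semicolon, tab, and whitespace,
#' and can be forced via `dialect`. Lines starting with `#` and blank lines
#' are skipped. Rows may arrive in descending axis order; the result is
#' always ascending.
#'
#' @param path File path.
#' @param dialect `"auto"` (default), `","`, `";"`, `"\t"`, or
#'   `"whitespace"`.
#' @param label Spectrum label; defaults to the file stem.
#' @return A [new_spectrum()] object.
#' @export
read_spectrum <- function(path, dialect = "auto", label = NULL) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (length(keep) < 2L) {
    stop("parse error in '", path, "': fewer than 2 data rows", call. = FALSE)
  }
  wn <- numeric(length(keep))
  it <- numeric(length(keep))
  for (j in seq_along(keep)) {
    ln <- keep[j]
    fields <- split_fields(lines[ln], dialect)
    if (length(fields) < 2L) {
      stop("parse error in '", path, "' at line ", ln,
           ": expected 2 columns", call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(fields[1:2]))
    if (any(is.na(vals))) {
      stop("parse error in '", path, "' at line ", ln,
           ": non-numeric value", call. = FALSE)
    }
    wn[j] <- vals[1L]
    it[j] <- vals[2L]
  }
  if (is.null(label)) label <- tools::file_path_sans_ext(basename(path))
  new_spectrum(wn, it, label = label)
}

#' Write a spectrum as two-column delimited text
#'
#' Values are written at full double precision so that a write/read cycle
#' round-trips within 1e-12.
#'
#' @param s A spectrum.
#' @param path Output path.
#' @param sep Field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path, sep = ",") {
  stopifnot(inherits(s, "specmend_spectrum"))
  lines <- paste(num_format(s$wavenumbers), num_format(s$intensities),
                 sep = sep)
  writeLines(lines, path)
  invisible(path)
}

# Full-precision text rendering of doubles (17 significant digits is
# sufficient for exact binary64 round-trip).
num_format <- function(x) formatC(x, digits = 17, format = "g", width = -1)

#' Resample a spectrum onto a target wavenumber grid
#'
#' Linear interpolation; outside the source range intensities are clamped to
#' the nearest edge value. Network inputs are produced by resampling all
#' spectra to a shared axis (1024 points by default elsewhere in the package).
#'
#' @param s A spectrum.
#' @param target_axis Ascending numeric grid overlapping the source axis.
#' @return A spectrum on `target_axis`.
#' @export
resample <- function(s, target_axis) {
  stopifnot(inherits(s, "specmend_spectrum"))
  target_axis <- as.numeric(target_axis)
  if (length(target_axis) < 2L || is.unsorted(target_axis, strictly = TRUE)) {
    stop("target_axis must be strictly ascending with >= 2 points",
         call. = FALSE)
  }
  if (max(target_axis) < min(s$wavenumbers) ||
      min(target_axis) > max(s$wavenumbers)) {
    stop("target_axis does not overlap the source axis", call. = FALSE)
  }
  yi <- stats::approx(s$wavenumbers, s$intensities, xout = target_axis,
                      method = "linear", rule = 2)$y
  new_spectrum(target_axis, yi, label = s$label, degenerate = s$degenerate)
}

#' Min-max normalize a spectrum to the 0-1 range
#'
#' Computes (x - min) / (max - min). A flat (degenerate) spectrum maps to all
#' zeros and the `degenerate` flag is set instead of raising, so batch jobs
#' never abort mid-run.
#'
#' @param s A spectrum.
#' @return A normalized spectrum.
#' @export
normalize_minmax <- function(s) {
  stopifnot(inherits(s, "specmend_spectrum"))
  sc <- normalize_minmax_vec(s$intensities)
  new_spectrum(s$wavenumbers, sc$x, label = s$label,
               degenerate = sc$degenerate)
}

# Vector core shared with SpectrumSet row normalization.
normalize_minmax_vec <- function(x) {
  lo <- min(x)
  hi <- max(x)
  if (hi - lo <= 0) {
    list(x = rep(0, length(x)), degenerate = TRUE)
  } else {
    list(x = (x - lo) / (hi - lo), degenerate = FALSE)
  }
}

#' Convert a reflectance pair to absorbance
#'
#' Background correction for reflectance measurements:
#' `-log10(sample / background)`, computed elementwise on identical axes.
#'
#' @param sample Sample spectrum.
#' @param background Background spectrum on the same axis, strictly positive.
#' @return Absorbance spectrum.
#' @export
absorbance_from_reflectance <- function(sample, background) {
  stopifnot(inherits(sample, "specmend_spectrum"),
            inherits(background, "specmend_spectrum"))
  if (length(sample$wavenumbers) != length(background$wavenumbers) ||
      any(sample$wavenumbers != background$wavenumbers)) {
    stop("sample and background must share an identical wavenumber axis",
         call. = FALSE)
  }
  bad <- which(sample$intensities <= 0 | background$intensities <= 0)
  if (length(bad) > 0L) {
    stop("nonpositive intensity at indices: ",
         paste(utils::head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) " ..." else "", call. = FALSE)
  }
  new_spectrum(sample$wavenumbers,
               -log10(sample$intensities / background$intensities),
               label = sample$label)
}

#' Default shared wavenumber axis
#'
#' Evenly spaced grid used for network inputs; defaults to 1024 points over
#' the mid-infrared fingerprint-through-stretch region.
#'
#' @param n Number of grid points (default 1024).
#' @param from,to Endpoints in cm^-1.
#' @return Numeric vector of length `n`.
#' @export
default_axis <- function(n = 1024L, from = 400, to = 4000) {
  seq(from, to, length.out = n)
}
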