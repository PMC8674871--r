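#' Construct a set of aligned spectra
#'
#' A SpectrumSet holds N spectra resampled onto one shared wavenumber axis as
#' an N x length(axis) intensity matrix. When `normalized` is TRUE every row
#' spans exactly 0-1, except rows flagged degenerate (flat inputs normalized
#' to zeros).
#'
#' @param axis Shared ascending wavenumber grid.
#' @param matrix Numeric matrix, one spectrum per row, ncol == length(axis).
#' @param labels Character vector of row identities (recycled if length 1).
#' @param normalized Logical: rows are min-max normalized.
#' @param degenerate Logical vector marking flat rows (default all FALSE).
#' @return An object of class `spectrum_set`.
#' @export
spectrum_set <- function(axis, matrix, labels = NULL, normalized = FALSE,
                         degenerate = NULL) {
  axis <- as.numeric(axis)
  if (!is.matrix(matrix)) matrix <- base::matrix(matrix, ncol = length(axis))
  storage.mode(matrix) <- "double"
  n <- nrow(matrix)
  if (ncol(matrix) != length(axis)) {
    stop("matrix width (", ncol(matrix), ") != axis length (",
         length(axis), ")", call. = FALSE)
  }
  if (length(axis) >= 2L && is.unsorted(axis, strictly = TRUE)) {
    stop("axis must be strictly ascending", call. = FALSE)
  }
  if (is.null(labels)) labels <- rep("spectrum", n)
  if (length(labels) == 1L && n > 1L) labels <- rep(labels, n)
  if (length(labels) != n) {
    stop("need one label per row", call. = FALSE)
  }
  if (is.null(degenerate)) degenerate <- rep(FALSE, n)
  if (length(degenerate) != n) {
    stop("need one degenerate flag per row", call. = FALSE)
  }
  structure(
    list(axis = axis, matrix = matrix, labels = as.character(labels),
         normalized = isTRUE(normalized), degenerate = as.logical(degenerate)),
    class = "spectrum_set"
  )
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set: %d spectra x %d wavenumbers%s>\n",
              nrow(x$matrix), length(x$axis),
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' @export
dim.spectrum_set <- function(x) dim(x$matrix)

#' Number of spectra in a set
#' @param set A `spectrum_set`.
#' @return Integer row count.
#' @export
n_spectra <- function(set) nrow(set$matrix)

#' Extract one row of a set as a spectrum
#' @param set A `spectrum_set`.
#' @param i Row index.
#' @return A [new_spectrum()] object.
#' @export
set_spectrum <- function(set, i) {
  new_spectrum(set$axis, set$matrix[i, ], label = set$labels[i],
               degenerate = set$degenerate[i])
}

#' Assemble spectra into a set on a common axis
#'
#' Each spectrum is resampled onto `axis` (defaults to 1024 evenly spaced
#' points spanning the intersection of all input axes) and optionally
#' min-max normalized.
#'
#' @param spectra List of spectra.
#' @param axis Target grid, or NULL to derive from the inputs.
#' @param n_points Grid width when `axis` is NULL.
#' @param normalize Min-max normalize each row (default TRUE).
#' @return A `spectrum_set`.
#' @export
as_spectrum_set <- function(spectra, axis = NULL, n_points = 1024L,
                            normalize = TRUE) {
  stopifnot(length(spectra) >= 1L)
  if (is.null(axis)) {
    lo <- max(vapply(spectra, function(s) min(s$wavenumbers), 0))
    hi <- min(vapply(spectra, function(s) max(s$wavenumbers), 0))
    if (hi <= lo) stop("input axes have empty intersection", call. = FALSE)
    axis <- seq(lo, hi, length.out = n_points)
  }
  mat <- base::matrix(0, length(spectra), length(axis))
  degen <- logical(length(spectra))
  for (i in seq_along(spectra)) {
    r <- resample(spectra[[i]], axis)
    if (normalize) {
      sc <- normalize_minmax_vec(r$intensities)
      mat[i, ] <- sc$x
      degen[i] <- sc$degenerate
    } else {
      mat[i, ] <- r$intensities
    }
  }
  spectrum_set(axis, mat,
               labels = vapply(spectra, function(s) s$label, ""),
               normalized = normalize, degenerate = degen)
}

#' Min-max normalize every row of a set
#' @param set A `spectrum_set`.
#' @return The set with each row spanning 0-1 (flat rows zeroed + flagged).
#' @export
normalize_set <- function(set) {
  stopifnot(inherits(set, "spectrum_set"))
  mat <- set$matrix
  degen <- logical(nrow(mat))
  for (i in seq_len(nrow(mat))) {
    sc <- normalize_minmax_vec(mat[i, ])
    mat[i, ] <- sc$x
    degen[i] <- sc$degenerate
  }
  spectrum_set(set$axis, mat, labels = set$labels, normalized = TRUE,
               degenerate = degen)
}

SET_FORMAT_VERSION <- "1"

#' Save / load a SpectrumSet
#'
#' Plain-text persistence: a small `#`-prefixed header (schema version, row
#' count, normalized flag, labels and degenerate flags as JSON) followed by
#' the axis and one tab-separated intensity row per spectrum, all at full
#' double precision, so save/load round-trips within 1e-12.
#'
#' @param set A `spectrum_set`.
#' @param path File path.
#' @return `save_set` returns `path` invisibly; `load_set` the restored set.
#' @export
save_set <- function(set, path) {
  stopifnot(inherits(set, "spectrum_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("#specmend-set\t", SET_FORMAT_VERSION),
    paste0("#nrow\t", nrow(set$matrix)),
    paste0("#normalized\t", as.integer(set$normalized)),
    paste0("#labels\t", as.character(jsonlite::toJSON(set$labels))),
    paste0("#degenerate\t",
           as.character(jsonlite::toJSON(as.integer(set$degenerate)))),
    paste0("#axis\t", paste(num_format(set$axis), collapse = "\t"))
  ), con)
  if (nrow(set$matrix) > 0L) {
    writeLines(apply(set$matrix, 1L,
                     function(r) paste(num_format(r), collapse = "\t")), con)
  }
  invisible(path)
}

#' @rdname save_set
#' @export
load_set <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  header <- grep("^#", lines, value = TRUE)
  get_field <- function(key) {
    hit <- header[startsWith(header, paste0("#", key, "\t"))]
    if (length(hit) != 1L) {
      stop("corrupt set file '", path, "': missing header field '", key, "'",
           call. = FALSE)
    }
    sub(paste0("^#", key, "\t"), "", hit)
  }
  if (get_field("specmend-set") != SET_FORMAT_VERSION) {
    stop("unsupported set file version in '", path, "'", call. = FALSE)
  }
  n <- as.integer(get_field("nrow"))
  normalized <- get_field("normalized") == "1"
  labels <- as.character(jsonlite::fromJSON(get_field("labels")))
  degenerate <- as.logical(as.integer(jsonlite::fromJSON(
    get_field("degenerate"))))
  axis <- as.numeric(strsplit(get_field("axis"), "\t", fixed = TRUE)[[1L]])
  rows <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(rows) != n) {
    stop("corrupt set file '", path, "': expected ", n, " rows, found ",
         length(rows), call. = FALSE)
  }
  mat <- base::matrix(0, n, length(axis))
  for (i in seq_len(n)) {
    vals <- as.numeric(strsplit(rows[i], "\t", fixed = TRUE)[[1L]])
    if (length(vals) != length(axis) || anyNA(vals)) {
      stop("corrupt set file '", path, "': bad data row ", i, call. = FALSE)
    }
    mat[i, ] <- vals
  }
  if (n == 0L) {
    labels <- character(0)
    degenerate <- logical(0)
  }
  spectrum_set(axis, mat, labels = labels, normalized = normalized,
               degenerate = degenerate)
}
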