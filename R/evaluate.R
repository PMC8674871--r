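#' Pearson correlation between two spectra
#'
#' Standard product-moment correlation of two equal-length intensity
#' vectors. If either vector is constant the correlation is undefined and
#' `NA` is returned; report builders exclude such pairs from summaries with
#' a warning rather than imputing a value.
#'
#' @param a,b Numeric vectors of equal length >= 2.
#' @return Correlation in `[-1, 1]`, or `NA` if undefined.
#' @export
pearson <- function(a, b) {
  if (length(a) != length(b)) {
    stop("length mismatch: ", length(a), " vs ", length(b), call. = FALSE)
  }
  if (length(a) < 2L) stop("need at least 2 points", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

# Per-row correlations between two aligned matrices; NA where undefined.
row_correlations <- function(A, B) {
  stopifnot(all(dim(A) == dim(B)))
  vapply(seq_len(nrow(A)), function(i) pearson(A[i, ], B[i, ]), 0)
}

#' Score reconstructions against their targets
#'
#' Computes the Pearson correlation of every reconstructed spectrum to its
#' aligned target; the distribution of these correlations is the measure of
#' reconstruction efficiency. Undefined correlations (constant rows) are
#' excluded from the summary and counted.
#'
#' @param recon,target Aligned `spectrum_set`s (same shape).
#' @param label Method label recorded in the report.
#' @return An `evaluation_report`: list with `methods`, `correlations`
#'   (one numeric vector per method), `summary` (data.frame of
#'   mean/median/quartiles/min/max per method) and `n_spectra`.
#' @export
correlation_report <- function(recon, target, label = "method") {
  stopifnot(inherits(recon, "spectrum_set"), inherits(target, "spectrum_set"))
  if (!all(dim(recon$matrix) == dim(target$matrix))) {
    stop("recon and target sets are misaligned: ",
         paste(dim(recon$matrix), collapse = "x"), " vs ",
         paste(dim(target$matrix), collapse = "x"), call. = FALSE)
  }
  r <- row_correlations(recon$matrix, target$matrix)
  new_evaluation_report(stats::setNames(list(r), label), nrow(recon$matrix))
}

new_evaluation_report <- function(correlations, n_spectra) {
  summaries <- lapply(names(correlations), function(m) {
    r <- correlations[[m]]
    n_undef <- sum(is.na(r))
    if (n_undef > 0L) {
      warning(n_undef, " undefined correlation(s) excluded from the '",
              m, "' summary", call. = FALSE)
    }
    r <- r[!is.na(r)]
    q <- if (length(r) > 0L) {
      stats::quantile(r, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    } else rep(NA_real_, 3L)
    data.frame(method = m, n = length(r), n_undefined = n_undef,
               mean = if (length(r)) mean(r) else NA_real_,
               q25 = q[1L], median = q[2L], q75 = q[3L],
               min = if (length(r)) min(r) else NA_real_,
               max = if (length(r)) max(r) else NA_real_)
  })
  structure(
    list(methods = names(correlations), correlations = correlations,
         summary = do.call(rbind, summaries), n_spectra = n_spectra),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report: %d spectra, %d method(s)>\n",
              x$n_spectra, length(x$methods)))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Merge evaluation reports over the same spectra
#' @param ... `evaluation_report`s with equal `n_spectra`.
#' @return A combined `evaluation_report`.
#' @export
merge_reports <- function(...) {
  reports <- list(...)
  n <- unique(vapply(reports, function(r) r$n_spectra, 0L))
  if (length(n) != 1L) {
    stop("reports cover different numbers of spectra", call. = FALSE)
  }
  corr <- do.call(c, lapply(reports, function(r) r$correlations))
  new_evaluation_report(corr, n)
}

#' Export an evaluation report
#'
#' Per-spectrum correlations go to CSV (one column per method); the summary
#' table to JSON.
#'
#' @param report An `evaluation_report`.
#' @param csv_path,json_path Output paths (either may be NULL to skip).
#' @return `report`, invisibly.
#' @export
write_report <- function(report, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "evaluation_report"))
  if (!is.null(csv_path)) {
    utils::write.csv(as.data.frame(report$correlations, check.names = FALSE),
                     csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(report$summary, json_path, digits = NA,
                         dataframe = "rows")
  }
  invisible(report)
}

#' Savitzky-Golay smoothing
#'
#' Classic least-squares polynomial smoothing in a sliding window: each
#' point is replaced by the value of the degree-`order` polynomial fitted to
#' the `window` points centered on it. Edge points are produced by
#' evaluating the polynomial fitted to the terminal windows. Defaults
#' (window 15 points, first-order polynomial) follow common FTIR denoising
#' practice.
#'
#' @param x Intensity vector.
#' @param window Odd window length in points (default 15).
#' @param order Polynomial degree, `< window` (default 1).
#' @return Smoothed vector of the same length.
#' @export
savitzky_golay <- function(x, window = 15L, order = 1L) {
  window <- as.integer(window)
  order <- as.integer(order)
  if (window %% 2L == 0L) stop("window must be odd", call. = FALSE)
  if (order >= window) stop("order must be < window", call. = FALSE)
  if (length(x) < window) {
    stop("signal shorter than the smoothing window", call. = FALSE)
  }
  as.numeric(signal::sgolayfilt(x, p = order, n = window))
}

#' Smooth every row of a set with Savitzky-Golay
#' @param set A `spectrum_set`.
#' @inheritParams savitzky_golay
#' @return A `spectrum_set` of smoothed rows.
#' @export
sg_smooth_set <- function(set, window = 15L, order = 1L) {
  stopifnot(inherits(set, "spectrum_set"))
  mat <- t(apply(set$matrix, 1L, savitzky_golay, window = window,
                 order = order))
  spectrum_set(set$axis, mat, labels = set$labels,
               normalized = FALSE, degenerate = set$degenerate)
}

#' Benchmark Savitzky-Golay parameters
#'
#' Smooths the noisy set with every valid (window, order) combination and
#' reports the mean Pearson correlation to the clean targets; combinations
#' with `order >= window` are omitted.
#'
#' @param noisy,clean Aligned `spectrum_set`s.
#' @param windows Odd window lengths to try.
#' @param orders Polynomial degrees to try.
#' @return data.frame with columns window, order, mean_correlation.
#' @export
sg_parameter_sweep <- function(noisy, clean, windows = c(5L, 9L, 15L, 21L),
                               orders = c(1L, 2L, 3L)) {
  stopifnot(inherits(noisy, "spectrum_set"), inherits(clean, "spectrum_set"))
  if (length(windows) == 0L || length(orders) == 0L) {
    stop("windows and orders must be nonempty", call. = FALSE)
  }
  if (!all(dim(noisy$matrix) == dim(clean$matrix))) {
    stop("noisy and clean sets are misaligned", call. = FALSE)
  }
  grid <- expand.grid(window = as.integer(windows),
                      order = as.integer(orders))
  grid <- grid[grid$order < grid$window, , drop = FALSE]
  grid$mean_correlation <- vapply(seq_len(nrow(grid)), function(i) {
    sm <- sg_smooth_set(noisy, grid$window[i], grid$order[i])
    mean(row_correlations(sm$matrix, clean$matrix), na.rm = TRUE)
  }, 0)
  rownames(grid) <- NULL
  grid
}

#' Select spectra reconstructed below a correlation threshold
#'
#' Returns the indices of rows whose Pearson correlation to the aligned
#' target is strictly below `threshold` — the rule used to isolate
#' hard-to-reconstruct spectra (e.g. keeping only spectra correlating below
#' 0.5 with their library target). Rows with undefined correlation are not
#' selected.
#'
#' @param set,targets Aligned `spectrum_set`s.
#' @param threshold Strict upper bound on the correlation.
#' @return Integer row indices.
#' @export
select_below_correlation <- function(set, targets, threshold) {
  stopifnot(inherits(set, "spectrum_set"), inherits(targets, "spectrum_set"))
  if (!all(dim(set$matrix) == dim(targets$matrix))) {
    stop("sets are misaligned", call. = FALSE)
  }
  r <- row_correlations(set$matrix, targets$matrix)
  which(!is.na(r) & r < threshold)
}

#' Compare autoencoder reconstruction against Savitzky-Golay smoothing
#'
#' Scores both methods on the same rows: the autoencoder reconstructions of
#' the noisy spectra and the Savitzky-Golay smoothed noisy spectra, each
#' correlated against the clean targets.
#'
#' @param noisy,clean Aligned `spectrum_set`s (noisy normalized).
#' @param model A trained `trained_model`.
#' @param sg_window,sg_order Savitzky-Golay parameters (defaults 15 / 1).
#' @return An `evaluation_report` with methods `"autoencoder"` and
#'   `"savitzky_golay"`.
#' @export
compare_methods <- function(noisy, clean, model, sg_window = 15L,
                            sg_order = 1L) {
  stopifnot(inherits(model, "trained_model"))
  if (!all(dim(noisy$matrix) == dim(clean$matrix))) {
    stop("noisy and clean sets are misaligned", call. = FALSE)
  }
  recon <- ae_reconstruct(model, noisy)
  sg <- sg_smooth_set(noisy, sg_window, sg_order)
  new_evaluation_report(
    list(autoencoder = row_correlations(recon$matrix, clean$matrix),
         savitzky_golay = row_correlations(sg$matrix, clean$matrix)),
    nrow(noisy$matrix))
}
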