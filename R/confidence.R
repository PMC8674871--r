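#' Mean distance to the k nearest training encodings
#'
#' For every test spectrum encoded in the latent space, computes the mean
#' Euclidean distance to its `k` nearest neighbours among the training
#' encodings. Large distances flag spectra unlike anything the network was
#' trained on, whose reconstructions deserve less trust. The default `k = 5`
#' averages over the five closest training spectra.
#'
#' @param test_codes N_test x D latent matrix.
#' @param train_codes N_train x D latent matrix (same width).
#' @param k Number of neighbours, `1 <= k <= nrow(train_codes)`.
#' @return Numeric vector of N_test nonnegative mean distances.
#' @export
knn_mean_distance <- function(test_codes, train_codes, k = 5L) {
  test_codes <- as.matrix(test_codes)
  train_codes <- as.matrix(train_codes)
  if (ncol(test_codes) != ncol(train_codes)) {
    stop("latent widths differ: ", ncol(test_codes), " vs ",
         ncol(train_codes), call. = FALSE)
  }
  k <- as.integer(k)
  if (k < 1L || k > nrow(train_codes)) {
    stop("k must be between 1 and the number of training encodings (",
         nrow(train_codes), ")", call. = FALSE)
  }
  if (nrow(test_codes) == 0L) return(numeric(0))
  tr_sq <- rowSums(train_codes^2)
  out <- numeric(nrow(test_codes))
  chunk <- 512L
  for (start in seq(1L, nrow(test_codes), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(test_codes))
    te <- test_codes[idx, , drop = FALSE]
    d2 <- outer(rowSums(te^2), tr_sq, "+") - 2 * te %*% t(train_codes)
    d2[d2 < 0] <- 0  # guard tiny negative rounding
    out[idx] <- apply(d2, 1L, function(row) {
      mean(sqrt(sort.int(row, partial = k)[seq_len(k)]))
    })
  }
  out
}

#' PCA diagnostics of the encoded space
#'
#' Fits a principal component analysis on the vertically combined train and
#' test encodings (a diagnostic visualization of how inference spectra sit
#' relative to the training cloud, not an estimator) and returns the test
#' rows' coordinates on the first three components plus the per-component
#' explained variance fractions. If the combined matrix has fewer than three
#' effective dimensions the missing columns are zero-padded with a warning.
#'
#' @param train_codes,test_codes Latent matrices of equal width.
#' @return List with `pca_coords` (N_test x 3) and `explained_variance`
#'   (length 3, fractions of total variance).
#' @export
pca_project <- function(train_codes, test_codes) {
  train_codes <- as.matrix(train_codes)
  test_codes <- as.matrix(test_codes)
  if (ncol(train_codes) != ncol(test_codes)) {
    stop("latent widths differ", call. = FALSE)
  }
  combined <- rbind(train_codes, test_codes)
  if (nrow(combined) < 3L) {
    stop("need at least 3 combined rows for a 3-component PCA",
         call. = FALSE)
  }
  fit <- stats::prcomp(combined, center = TRUE, scale. = FALSE)
  n_pc <- ncol(fit$rotation)
  var_frac <- fit$sdev^2 / sum(fit$sdev^2)
  coords <- base::matrix(0, nrow(test_codes), 3L)
  ev <- numeric(3L)
  take <- min(3L, n_pc)
  test_scores <- fit$x[seq(nrow(train_codes) + 1L, nrow(combined)), ,
                       drop = FALSE]
  coords[, seq_len(take)] <- test_scores[, seq_len(take), drop = FALSE]
  ev[seq_len(take)] <- var_frac[seq_len(take)]
  if (take < 3L) {
    warning("combined encodings have rank < 3; padding components with zeros",
            call. = FALSE)
  }
  list(pca_coords = coords, explained_variance = ev)
}

#' Accept reconstructions within a distance threshold
#'
#' @param distances Nonnegative latent kNN distances.
#' @param threshold User-defined acceptance bound (may be `Inf`); no default
#'   is shipped because a useful bound depends on the training data.
#' @return Logical mask, TRUE where `distance <= threshold`.
#' @export
filter_by_distance <- function(distances, threshold) {
  if (length(threshold) != 1L || is.na(threshold) || threshold < 0) {
    stop("threshold must be a single nonnegative number (or Inf)",
         call. = FALSE)
  }
  distances <= threshold
}

#' Assemble a confidence screening result
#'
#' Bundles latent kNN distances, the acceptance mask for a user-defined
#' threshold, and PCA diagnostics of the encoded space.
#'
#' @param model A trained `trained_model`.
#' @param train_set,test_set Normalized `spectrum_set`s on the training axis.
#' @param k Neighbour count (default 5).
#' @param threshold Acceptance bound on the mean distance (default `Inf`,
#'   accepting everything until the user picks a bound).
#' @return An object of class `confidence_result`: distances, k, threshold,
#'   accepted mask, `pca_coords` (N_test x 3), `explained_variance`.
#' @export
confidence_screen <- function(model, train_set, test_set, k = 5L,
                              threshold = Inf) {
  train_codes <- ae_encode(model, train_set)
  test_codes <- ae_encode(model, test_set)
  distances <- knn_mean_distance(test_codes, train_codes, k = k)
  pca <- pca_project(train_codes, test_codes)
  structure(
    list(distances = distances, k = as.integer(k), threshold = threshold,
         accepted_mask = filter_by_distance(distances, threshold),
         pca_coords = pca$pca_coords,
         explained_variance = pca$explained_variance,
         n_train = nrow(train_codes), n_test = nrow(test_codes)),
    class = "confidence_result"
  )
}

#' @export
print.confidence_result <- function(x, ...) {
  cat(sprintf(
    "<confidence_result: %d test vs %d train encodings, k=%d, %d/%d accepted>\n",
    x$n_test, x$n_train, x$k, sum(x$accepted_mask), x$n_test))
  invisible(x)
}

#' Export a confidence result to CSV
#'
#' Writes one row per test spectrum: distance, accepted flag, and the three
#' PCA coordinates, for external plotting.
#'
#' @param result A `confidence_result`.
#' @param path Output CSV path.
#' @return `result`, invisibly.
#' @export
write_confidence <- function(result, path) {
  stopifnot(inherits(result, "confidence_result"))
  df <- data.frame(distance = result$distances,
                   accepted = result$accepted_mask,
                   pc1 = result$pca_coords[, 1L],
                   pc2 = result$pca_coords[, 2L],
                   pc3 = result$pca_coords[, 3L])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(result)
}
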