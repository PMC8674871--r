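#' Configuration for a benchmark experiment
#'
#' Describes how to build the training and testing datasets (disjoint base
#' spectra, variation counts, distortion parameters), how to train, and
#' where to write outputs. Train and test bases are generated from disjoint
#' seed ranges and additionally checked for row identity before training.
#'
#' @param n_train_bases,n_test_bases Number of synthetic base spectra per
#'   split. The default training library (400 bases) is larger than a
#'   curated reference library would be because the synthetic band
#'   vocabulary is sampled more diversely than real polymer classes; see
#'   the package vignette.
#' @param n_train_variations,n_test_variations Distorted replicates per
#'   base.
#' @param train_distortion,test_distortion [distortion_spec()]s per split;
#'   `test_distortion` defaults to the training family (with its own seed).
#'   The default noise range reaches high levels (sigma up to 0.6 on
#'   unit-height spectra) where window smoothing visibly fails.
#' @param train_cfg A [train_config()]; the benchmark default disables
#'   dropout, which is only warranted against strong overfitting.
#' @param axis Shared wavenumber grid (default 1024 points, 400-4000 cm^-1).
#' @param peak_range `(lo, hi)` peaks per synthetic base spectrum.
#' @param output_dir Directory for reports/models/logs, or NULL to skip
#'   writing.
#' @param seed Global seed; base-spectrum seeds and per-split distortion
#'   seeds derive from it.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(n_train_bases = 400L,
                              n_train_variations = 20L,
                              n_test_bases = 20L, n_test_variations = 50L,
                              train_distortion = distortion_spec(
                                noise_sigma = c(0.05, 0.6)),
                              test_distortion = NULL,
                              train_cfg = train_config(epochs = 100L,
                                                       dropout_rate = 0),
                              axis = default_axis(),
                              peak_range = c(3L, 12L),
                              output_dir = NULL, seed = 1L) {
  stopifnot(n_train_bases >= 1L, n_test_bases >= 1L,
            n_train_variations >= 1L, n_test_variations >= 1L,
            inherits(train_distortion, "distortion_spec"),
            inherits(train_cfg, "train_config"),
            length(peak_range) == 2L, peak_range[1L] <= peak_range[2L])
  structure(
    list(n_train_bases = as.integer(n_train_bases),
         n_train_variations = as.integer(n_train_variations),
         n_test_bases = as.integer(n_test_bases),
         n_test_variations = as.integer(n_test_variations),
         train_distortion = train_distortion,
         test_distortion = test_distortion,
         train_cfg = train_cfg, axis = as.numeric(axis),
         peak_range = as.integer(peak_range),
         output_dir = output_dir, seed = as.integer(seed)),
    class = "experiment_config"
  )
}

# Tiny FNV-1a hash of a config's JSON rendering, for run logging.
config_hash <- function(config) {
  bytes <- utf8ToInt(as.character(jsonlite::toJSON(
    rapply(unclass(config), unclass, how = "replace"), auto_unbox = TRUE,
    digits = NA, force = TRUE)))
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

make_logger <- function(output_dir, run_id) {
  log_path <- if (!is.null(output_dir)) {
    file.path(output_dir, paste0(run_id, ".log"))
  } else NULL
  function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...))
    message(line)
    if (!is.null(log_path)) cat(line, "\n", file = log_path, append = TRUE)
  }
}

# Generate the disjoint train/test base-spectrum sets for a config. Train
# bases use seeds offset+1..offset+n_train; test bases continue after them,
# so the two splits never share a generator seed.
make_base_sets <- function(config) {
  gen <- function(idx, prefix) {
    old <- local_seed(derive_row_seed(config$seed, idx))
    n_pk <- sample(seq(config$peak_range[1L], config$peak_range[2L]), 1L)
    restore_seed(old)
    generate_base_spectrum(n_pk, axis = config$axis,
                           seed = derive_row_seed(config$seed + 7L, idx),
                           label = sprintf("%s_base_%03d", prefix, idx))
  }
  train <- lapply(seq_len(config$n_train_bases), gen, prefix = "train")
  test <- lapply(
    config$n_train_bases + seq_len(config$n_test_bases), gen,
    prefix = "test")
  train_set <- as_spectrum_set(train, axis = config$axis, normalize = TRUE)
  test_set <- as_spectrum_set(test, axis = config$axis, normalize = TRUE)
  assert_disjoint_bases(train_set, test_set)
  list(train = train_set, test = test_set)
}

# Identity check: no test base row may equal any train base row.
assert_disjoint_bases <- function(train_set, test_set) {
  keys_tr <- apply(round(train_set$matrix, 12L), 1L, paste, collapse = ",")
  keys_te <- apply(round(test_set$matrix, 12L), 1L, paste, collapse = ",")
  if (any(keys_te %in% keys_tr)) {
    stop("train and test base sets overlap; they must be disjoint",
         call. = FALSE)
  }
  invisible(TRUE)
}

prepare_output <- function(config, verb) {
  run_id <- sprintf("%s_%s_seed%d", verb, config_hash(config), config$seed)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  }
  log <- make_logger(config$output_dir, run_id)
  log("run %s (config hash %s, seed %d)", run_id, config_hash(config),
      config$seed)
  list(run_id = run_id, log = log)
}

#' Run the denoising benchmark
#'
#' End-to-end replication of the noise-reduction benchmark: build a
#' training dataset (`n_train_bases x n_train_variations`) and a disjoint
#' test dataset, train the autoencoder on the training pairs, reconstruct
#' the test spectra, and score both the autoencoder and a Savitzky-Golay
#' smoother (window 15, order 1) against the clean targets.
#'
#' @param config An [experiment_config()].
#' @param quiet Suppress per-epoch training output.
#' @return List: `report` (`evaluation_report` for both methods), `model`,
#'   `train_data`, `test_data`.
#' @export
run_denoise_benchmark <- function(config = experiment_config(),
                                  quiet = TRUE) {
  stopifnot(inherits(config, "experiment_config"))
  out <- prepare_output(config, "benchmark")
  log <- out$log

  bases <- make_base_sets(config)
  log("bases: %d train, %d test (disjoint)", n_spectra(bases$train),
      n_spectra(bases$test))

  train_spec <- config$train_distortion
  test_spec <- if (is.null(config$test_distortion)) {
    ts <- train_spec
    ts$seed <- train_spec$seed + 101L
    ts
  } else config$test_distortion

  train_data <- build_dataset(bases$train, config$n_train_variations,
                              train_spec)
  test_data <- build_dataset(bases$test, config$n_test_variations, test_spec)
  log("datasets: %d training rows, %d testing rows",
      nrow(train_data$noisy$matrix), nrow(test_data$noisy$matrix))

  model <- ae_train(NULL, train_data, config$train_cfg, quiet = quiet)
  log("trained %d epochs (best val loss %.6f)", nrow(model$history),
      min(model$history$val_loss))

  report <- compare_methods(test_data$noisy, test_data$clean, model)
  log("mean correlation: AE %.4f, SG %.4f",
      report$summary$mean[report$summary$method == "autoencoder"],
      report$summary$mean[report$summary$method == "savitzky_golay"])

  if (!is.null(config$output_dir)) {
    write_report(report,
                 csv_path = file.path(config$output_dir,
                                      paste0(out$run_id, "_correlations.csv")),
                 json_path = file.path(config$output_dir,
                                       paste0(out$run_id, "_summary.json")))
    save_model(model, file.path(config$output_dir,
                                paste0(out$run_id, "_model")))
  }
  list(report = report, model = model, train_data = train_data,
       test_data = test_data)
}

#' Run the mismatched-training experiment
#'
#' Trains on distortion family A and evaluates on two test sets built from
#' the same held-out bases: one distorted by family A (matched) and one by
#' family B (mismatched). A network confronted with artifact types absent
#' from its training data reconstructs markedly worse — the degradation seen
#' when a model trained on synthetic ATR distortions is applied to real
#' micro-FTIR particle spectra.
#'
#' @param config An [experiment_config()] whose `train_distortion` is family
#'   A.
#' @param mismatch_distortion Family B [distortion_spec()]; the shipped
#'   default tests a noise-only-trained model on spectra that additionally
#'   carry fluorescence humps and periodic interference.
#' @param quiet Suppress training output.
#' @return List: `matched` and `mismatched` (`evaluation_report`s on equal
#'   row counts), `difference` (matched mean - mismatched mean), `model`.
#' @export
run_mismatch_experiment <- function(
    config = experiment_config(
      n_train_bases = 200L, n_train_variations = 20L,
      train_distortion = distortion_spec(noise_sigma = c(0.01, 0.10)),
      train_cfg = train_config(epochs = 60L, dropout_rate = 0)),
    mismatch_distortion = distortion_spec(
      noise_sigma = c(0.01, 0.10), fluorescence_amp = 1.0,
      interference_amp = 0.3, interference_period = 120, seed = 909L),
    quiet = TRUE) {
  stopifnot(inherits(config, "experiment_config"),
            inherits(mismatch_distortion, "distortion_spec"))
  out <- prepare_output(config, "mismatch")
  log <- out$log
  if (identical(unclass(config$train_distortion)[names(unclass(config$train_distortion)) != "seed"],
                unclass(mismatch_distortion)[names(unclass(mismatch_distortion)) != "seed"])) {
    warning("mismatch distortion family is identical to the training family",
            call. = FALSE)
  }

  bases <- make_base_sets(config)
  train_spec <- config$train_distortion
  matched_spec <- train_spec
  matched_spec$seed <- train_spec$seed + 101L

  train_data <- build_dataset(bases$train, config$n_train_variations,
                              train_spec)
  matched_data <- build_dataset(bases$test, config$n_test_variations,
                                matched_spec)
  mismatched_data <- build_dataset(bases$test, config$n_test_variations,
                                   mismatch_distortion)
  model <- ae_train(NULL, train_data, config$train_cfg, quiet = quiet)

  matched <- correlation_report(ae_reconstruct(model, matched_data$noisy),
                                matched_data$clean, label = "matched")
  mismatched <- correlation_report(
    ae_reconstruct(model, mismatched_data$noisy),
    mismatched_data$clean, label = "mismatched")
  diff <- matched$summary$mean - mismatched$summary$mean
  log("matched mean %.4f, mismatched mean %.4f, difference %.4f",
      matched$summary$mean, mismatched$summary$mean, diff)

  if (!is.null(config$output_dir)) {
    write_report(merge_reports(matched, mismatched),
                 csv_path = file.path(config$output_dir,
                                      paste0(out$run_id, "_correlations.csv")),
                 json_path = file.path(config$output_dir,
                                       paste0(out$run_id, "_summary.json")))
  }
  list(matched = matched, mismatched = mismatched, difference = diff,
       model = model)
}

#' Run the latent-space confidence study
#'
#' Trains on the training dataset, encodes both training and testing
#' spectra, computes each test spectrum's mean distance to its `k = 5`
#' nearest training encodings, fits the combined-encodings PCA, and pairs
#' every distance with the reconstruction correlation of the same spectrum.
#' The Spearman rank correlation between distance and reconstruction
#' quality summarizes the (negative) trend: reconstructions degrade with
#' distance from the training data.
#'
#' @param config An [experiment_config()]; the shipped default uses 80
#'   training bases x 100 variations (8000 encodings) and 20 test bases x
#'   100 (2000 encodings).
#' @param k Neighbour count (default 5).
#' @param quiet Suppress training output.
#' @return List: `confidence` (`confidence_result`), `report`
#'   (`evaluation_report` of the reconstructions), `spearman` (distance vs
#'   correlation), `model`.
#' @export
run_confidence_study <- function(
    config = experiment_config(n_train_bases = 80L,
                               n_train_variations = 100L,
                               n_test_bases = 20L, n_test_variations = 100L,
                               train_distortion = distortion_spec(
                                 noise_sigma = c(0.01, 0.15),
                                 baseline_amp = 0.3),
                               train_cfg = train_config(epochs = 60L,
                                                        dropout_rate = 0)),
    k = 5L, quiet = TRUE) {
  stopifnot(inherits(config, "experiment_config"))
  out <- prepare_output(config, "confidence")
  log <- out$log

  bases <- make_base_sets(config)
  train_spec <- config$train_distortion
  test_spec <- if (is.null(config$test_distortion)) {
    ts <- train_spec
    ts$seed <- train_spec$seed + 101L
    ts
  } else config$test_distortion

  train_data <- build_dataset(bases$train, config$n_train_variations,
                              train_spec)
  test_data <- build_dataset(bases$test, config$n_test_variations, test_spec)
  model <- ae_train(NULL, train_data, config$train_cfg, quiet = quiet)

  conf <- confidence_screen(model, train_data$noisy, test_data$noisy, k = k)
  report <- correlation_report(ae_reconstruct(model, test_data$noisy),
                               test_data$clean, label = "autoencoder")
  rho <- stats::cor(conf$distances, report$correlations[[1L]],
                    method = "spearman", use = "complete.obs")
  log("encodings: %d train + %d test; Spearman(distance, correlation) = %.4f",
      conf$n_train, conf$n_test, rho)

  if (!is.null(config$output_dir)) {
    write_confidence(conf, file.path(config$output_dir,
                                     paste0(out$run_id, "_confidence.csv")))
    write_report(report,
                 csv_path = file.path(config$output_dir,
                                      paste0(out$run_id, "_correlations.csv")),
                 json_path = file.path(config$output_dir,
                                       paste0(out$run_id, "_summary.json")))
  }
  list(confidence = conf, report = report, spearman = rho, model = model)
}
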