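#' Training configuration for the reconstruction autoencoder
#'
#' The network is a shallow densely connected autoencoder: the encoder maps
#' an input spectrum from `input_width` (default 1024) wavenumbers down to
#' `latent_dim` (default 128) latent dimensions, and the decoder expands back
#' to `input_width`. Dropout stages (rate `dropout_rate`, default 0.15) sit
#' after the input and after the latent layer to curb overfitting; setting
#' the rate to 0 disables them. Hidden activation is rectified-linear, the
#' output activation is a logistic sigmoid so reconstructions always lie in
#' the 0-1 range of normalized spectra, and the loss is mean squared error
#' minimized by Adam.
#'
#' @param input_width Spectrum width (default 1024).
#' @param latent_dim Latent width (default 128), must be < `input_width`.
#' @param dropout_rate In `[0, 1)`; 0 disables dropout (default 0.15).
#' @param epochs Maximum training epochs.
#' @param batch_size Minibatch size (default 32).
#' @param learning_rate Adam step size (default 1e-3).
#' @param seed Integer seed: weight init, shuffling and dropout masks all
#'   derive from it, so a fixed seed gives bit-stable training.
#' @param validation_split Fraction of rows held out for validation
#'   (default 0.1).
#' @param early_stop_patience Stop after this many epochs without validation
#'   improvement (default 10); the best-validation weights are restored.
#' @return An object of class `train_config`.
#' @export
train_config <- function(input_width = 1024L, latent_dim = 128L,
                         dropout_rate = 0.15, epochs = 100L, batch_size = 32L,
                         learning_rate = 1e-3, seed = 1L,
                         validation_split = 0.1, early_stop_patience = 10L) {
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("dropout_rate must be in [0, 1)", call. = FALSE)
  }
  if (latent_dim >= input_width) {
    stop("latent_dim must be smaller than input_width", call. = FALSE)
  }
  if (epochs < 1L) stop("epochs must be >= 1", call. = FALSE)
  stopifnot(batch_size >= 1L, learning_rate > 0,
            validation_split >= 0, validation_split < 1)
  structure(
    list(input_width = as.integer(input_width),
         latent_dim = as.integer(latent_dim),
         dropout_rate = as.numeric(dropout_rate),
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         learning_rate = as.numeric(learning_rate), seed = as.integer(seed),
         validation_split = as.numeric(validation_split),
         early_stop_patience = as.integer(early_stop_patience),
         loss = "mse"),
    class = "train_config"
  )
}

#' Build an (untrained) reconstruction autoencoder
#'
#' Allocates Glorot-uniform initialized weights for the dense encoder
#' (`input_width -> latent_dim`) and decoder (`latent_dim -> input_width`).
#'
#' @param config A [train_config()].
#' @param training_axis Optional wavenumber grid of length `input_width`,
#'   recorded so reconstruction requests on a different grid can be caught.
#' @return An object of class `trained_model` with `trained = FALSE`.
#' @export
build_autoencoder <- function(config = train_config(), training_axis = NULL) {
  stopifnot(inherits(config, "train_config"))
  if (!is.null(training_axis) &&
      length(training_axis) != config$input_width) {
    stop("training_axis length must equal input_width", call. = FALSE)
  }
  old <- local_seed(config$seed)
  on.exit(restore_seed(old))
  glorot <- function(n_in, n_out) {
    lim <- sqrt(6 / (n_in + n_out))
    base::matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
  }
  structure(
    list(
      W1 = glorot(config$input_width, config$latent_dim),
      b1 = numeric(config$latent_dim),
      W2 = glorot(config$latent_dim, config$input_width),
      b2 = numeric(config$input_width),
      config = config,
      training_axis = if (is.null(training_axis)) NULL
        else as.numeric(training_axis),
      dropout_stages = if (config$dropout_rate > 0) {
        list(after_input = config$dropout_rate,
             after_latent = config$dropout_rate)
      } else list(),
      history = NULL,
      trained = FALSE
    ),
    class = "trained_model"
  )
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf(
    "<autoencoder %d -> %d -> %d, dropout %.2f, %s>\n",
    x$config$input_width, x$config$latent_dim, x$config$input_width,
    x$config$dropout_rate,
    if (x$trained) sprintf("trained (%d epochs)", nrow(x$history))
    else "untrained"))
  invisible(x)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Forward pass in inference mode (dropout inactive, deterministic).
ae_forward <- function(model, X) {
  H <- pmax(sweep(X %*% model$W1, 2L, model$b1, "+"), 0)
  Y <- sigmoid(sweep(H %*% model$W2, 2L, model$b2, "+"))
  list(H = H, Y = Y)
}

#' Train the autoencoder on a paired dataset
#'
#' Minimizes the mean squared error between `reconstruct(noisy)` and the
#' aligned clean targets by minibatch Adam. A validation fraction is split
#' off (by shuffled row indices under the config seed); per-epoch train and
#' validation losses are recorded, and the weights of the best-validation
#' epoch are restored at the end. The learning rate is halved whenever the
#' validation loss stalls for 5 consecutive epochs (plateau schedule, floor
#' 1e-5), and training stops early after `early_stop_patience` epochs
#' without validation improvement.
#'
#' @param model A model from [build_autoencoder()] (or NULL to build one
#'   from `config`).
#' @param data A `paired_dataset` with normalized, aligned noisy/clean sets.
#' @param config A [train_config()]; defaults to `model$config`.
#' @param quiet Suppress the per-epoch progress line.
#' @return The trained `trained_model`, with `history` (data.frame of
#'   epoch/train_loss/val_loss) attached.
#' @export
ae_train <- function(model = NULL, data, config = NULL, quiet = TRUE) {
  stopifnot(inherits(data, "paired_dataset"))
  if (is.null(config)) {
    config <- if (is.null(model)) train_config() else model$config
  }
  if (is.null(model)) {
    model <- build_autoencoder(config, training_axis = data$noisy$axis)
  }
  X_all <- data$noisy$matrix
  T_all <- data$clean$matrix
  if (ncol(X_all) != config$input_width) {
    stop("dataset width ", ncol(X_all), " != input_width ",
         config$input_width, "; resample first", call. = FALSE)
  }
  if (!data$noisy$normalized || !data$clean$normalized) {
    stop("training data must be min-max normalized", call. = FALSE)
  }
  if (is.null(model$training_axis)) model$training_axis <- data$noisy$axis
  n <- nrow(X_all)

  old <- local_seed(config$seed + 1L)
  on.exit(restore_seed(old))

  perm <- sample.int(n)
  n_val <- floor(config$validation_split * n)
  val_idx <- if (n_val > 0L) perm[seq_len(n_val)] else integer(0)
  tr_idx <- if (n_val > 0L) perm[-seq_len(n_val)] else perm
  Xv <- X_all[val_idx, , drop = FALSE]
  Tv <- T_all[val_idx, , drop = FALSE]
  has_val <- n_val > 0L

  W <- list(W1 = model$W1, b1 = model$b1, W2 = model$W2, b2 = model$b2)
  mom <- lapply(W, function(w) w * 0)
  vel <- lapply(W, function(w) w * 0)
  lr <- config$learning_rate
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  p <- config$dropout_rate
  t_step <- 0

  best_val <- Inf
  best_W <- W
  patience_left <- config$early_stop_patience
  plateau_left <- 5L
  hist_train <- numeric(0)
  hist_val <- numeric(0)

  for (epoch in seq_len(config$epochs)) {
    order_ep <- tr_idx[sample.int(length(tr_idx))]
    ep_loss <- 0
    ep_n <- 0L
    for (b0 in seq(1L, length(order_ep), by = config$batch_size)) {
      rows <- order_ep[b0:min(b0 + config$batch_size - 1L, length(order_ep))]
      X <- X_all[rows, , drop = FALSE]
      Tt <- T_all[rows, , drop = FALSE]
      nb <- nrow(X)

      # inverted dropout after input and after the latent layer
      if (p > 0) {
        mask_in <- base::matrix(
          (stats::runif(nb * ncol(X)) >= p) / (1 - p), nb, ncol(X))
        Xd <- X * mask_in
      } else Xd <- X
      A1 <- sweep(Xd %*% W$W1, 2L, W$b1, "+")
      H <- pmax(A1, 0)
      if (p > 0) {
        mask_lat <- base::matrix(
          (stats::runif(nb * ncol(H)) >= p) / (1 - p), nb, ncol(H))
        Hd <- H * mask_lat
      } else Hd <- H
      Y <- sigmoid(sweep(Hd %*% W$W2, 2L, W$b2, "+"))

      err <- Y - Tt
      ep_loss <- ep_loss + sum(err^2)
      ep_n <- ep_n + length(err)

      dZ2 <- (2 / length(err)) * err * Y * (1 - Y)
      gW2 <- crossprod(Hd, dZ2)
      gb2 <- colSums(dZ2)
      dHd <- dZ2 %*% t(W$W2)
      dH <- if (p > 0) dHd * mask_lat else dHd
      dA1 <- dH * (A1 > 0)
      gW1 <- crossprod(Xd, dA1)
      gb1 <- colSums(dA1)

      t_step <- t_step + 1
      grads <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
      corr1 <- 1 - beta1^t_step
      corr2 <- 1 - beta2^t_step
      for (k in names(W)) {
        mom[[k]] <- beta1 * mom[[k]] + (1 - beta1) * grads[[k]]
        vel[[k]] <- beta2 * vel[[k]] + (1 - beta2) * grads[[k]]^2
        W[[k]] <- W[[k]] -
          lr * (mom[[k]] / corr1) / (sqrt(vel[[k]] / corr2) + eps)
      }
    }
    train_loss <- ep_loss / ep_n
    model_now <- utils::modifyList(model, W)
    val_loss <- if (has_val) {
      mean((ae_forward(model_now, Xv)$Y - Tv)^2)
    } else train_loss
    if (!is.finite(train_loss) || !is.finite(val_loss)) {
      stop("training diverged: non-finite loss at epoch ", epoch,
           " (train=", train_loss, ", val=", val_loss, ")", call. = FALSE)
    }
    hist_train <- c(hist_train, train_loss)
    hist_val <- c(hist_val, val_loss)
    if (!quiet) {
      message(sprintf("epoch %3d  train %.6f  val %.6f", epoch,
                      train_loss, val_loss))
    }
    if (val_loss < best_val - 1e-12) {
      best_val <- val_loss
      best_W <- W
      patience_left <- config$early_stop_patience
      plateau_left <- 5L
    } else {
      patience_left <- patience_left - 1L
      plateau_left <- plateau_left - 1L
      if (patience_left <= 0L) break
      if (plateau_left <= 0L && lr > 1e-5) {
        lr <- max(lr * 0.5, 1e-5)
        plateau_left <- 5L
      }
    }
  }

  model$W1 <- best_W$W1; model$b1 <- best_W$b1
  model$W2 <- best_W$W2; model$b2 <- best_W$b2
  model$config <- config
  model$history <- data.frame(epoch = seq_along(hist_train),
                              train_loss = hist_train, val_loss = hist_val)
  model$trained <- TRUE
  model
}

check_width <- function(model, set) {
  if (ncol(set$matrix) != model$config$input_width) {
    stop("input width ", ncol(set$matrix), " != model input_width ",
         model$config$input_width,
         "; resample the spectra onto the training axis first",
         call. = FALSE)
  }
}

#' Reconstruct spectra with a trained autoencoder
#'
#' Runs the encoder/decoder in inference mode (dropout inactive), so two
#' calls on the same input give identical output. Outputs always lie in
#' 0-1 thanks to the sigmoid output stage.
#'
#' @param model A `trained_model`.
#' @param noisy A normalized `spectrum_set` of width `input_width`.
#' @return A `spectrum_set` of reconstructions, same shape and labels.
#' @export
ae_reconstruct <- function(model, noisy) {
  stopifnot(inherits(model, "trained_model"), inherits(noisy, "spectrum_set"))
  check_width(model, noisy)
  Y <- ae_forward(model, noisy$matrix)$Y
  spectrum_set(noisy$axis, Y, labels = noisy$labels, normalized = TRUE,
               degenerate = rep(FALSE, nrow(Y)))
}

#' Encode spectra into the latent space
#'
#' @param model A `trained_model`.
#' @param set A normalized `spectrum_set` of width `input_width`.
#' @return N x `latent_dim` numeric matrix of latent codes (deterministic in
#'   inference mode).
#' @export
ae_encode <- function(model, set) {
  stopifnot(inherits(model, "trained_model"), inherits(set, "spectrum_set"))
  check_width(model, set)
  if (nrow(set$matrix) == 0L) {
    return(base::matrix(0, 0L, model$config$latent_dim))
  }
  ae_forward(model, set$matrix)$H
}

MODEL_FORMAT_VERSION <- "1"

#' Save / load a trained model
#'
#' A model is persisted as a directory: `metadata.json` (schema version,
#' config, training axis, history) plus one full-precision text file per
#' parameter array, so reconstructions before and after a round-trip agree
#' within 1e-6 (in practice, exactly).
#'
#' @param model A `trained_model`.
#' @param path Directory path (created if needed).
#' @return `save_model` returns `path` invisibly; `load_model` the restored
#'   model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "trained_model"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    schema_version = MODEL_FORMAT_VERSION,
    config = unclass(model$config),
    training_axis = model$training_axis,
    dropout_stages = model$dropout_stages,
    trained = model$trained,
    history = model$history
  )
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  write_param <- function(w, name) {
    con <- file(file.path(path, paste0(name, ".tsv")), "w")
    on.exit(close(con))
    w <- as.matrix(w)
    writeLines(paste0("#dim\t", nrow(w), "\t", ncol(w)), con)
    writeLines(apply(w, 1L, function(r) paste(num_format(r), collapse = "\t")),
               con)
  }
  write_param(model$W1, "W1"); write_param(model$b1, "b1")
  write_param(model$W2, "W2"); write_param(model$b2, "b2")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  meta_path <- file.path(path, "metadata.json")
  if (!file.exists(meta_path)) {
    stop("not a model directory (missing metadata.json): ", path,
         call. = FALSE)
  }
  meta <- jsonlite::fromJSON(meta_path)
  if (!identical(as.character(meta$schema_version), MODEL_FORMAT_VERSION)) {
    stop("unsupported model schema version in ", path, call. = FALSE)
  }
  cfg <- meta$config
  config <- train_config(
    input_width = cfg$input_width, latent_dim = cfg$latent_dim,
    dropout_rate = cfg$dropout_rate, epochs = cfg$epochs,
    batch_size = cfg$batch_size, learning_rate = cfg$learning_rate,
    seed = cfg$seed, validation_split = cfg$validation_split,
    early_stop_patience = cfg$early_stop_patience)
  read_param <- function(name) {
    lines <- readLines(file.path(path, paste0(name, ".tsv")), warn = FALSE)
    dims <- as.integer(strsplit(lines[1L], "\t", fixed = TRUE)[[1L]][2:3])
    vals <- lapply(lines[-1L],
                   function(l) as.numeric(strsplit(l, "\t", fixed = TRUE)[[1L]]))
    m <- do.call(rbind, vals)
    if (!all(dim(m) == dims)) {
      stop("corrupt parameter file ", name, ".tsv in ", path, call. = FALSE)
    }
    m
  }
  model <- build_autoencoder(config)
  model$W1 <- read_param("W1")
  model$b1 <- as.numeric(read_param("b1"))
  model$W2 <- read_param("W2")
  model$b2 <- as.numeric(read_param("b2"))
  model$training_axis <- if (is.null(meta$training_axis)) NULL
    else as.numeric(meta$training_axis)
  model$trained <- isTRUE(meta$trained)
  if (!is.null(meta$history) && length(meta$history) > 0) {
    model$history <- as.data.frame(meta$history)
  }
  model
}
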