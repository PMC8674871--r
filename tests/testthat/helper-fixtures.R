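# Shared fixtures: everything is generated in code at test time.

# Small axis keeps unit-test models fast; benchmarks use the full 1024 grid.
tiny_axis <- function(n = 64L) seq(400, 4000, length.out = n)

# A small set of synthetic clean bases on a given axis.
make_bases <- function(n_bases, axis = tiny_axis(), seed0 = 100L) {
  spectra <- lapply(seq_len(n_bases), function(i) {
    generate_base_spectrum(5L, axis = axis, seed = seed0 + i,
                           label = paste0("base", i))
  })
  as_spectrum_set(spectra, axis = axis, normalize = TRUE)
}

# A quickly trainable config for unit tests on the tiny axis.
tiny_train_config <- function(...) {
  args <- list(input_width = 64L, latent_dim = 16L, dropout_rate = 0,
               epochs = 30L, batch_size = 16L, seed = 11L,
               validation_split = 0.1, early_stop_patience = 30L)
  over <- list(...)
  args[names(over)] <- over
  do.call(train_config, args)
}

# Direct-formula Pearson oracle, independent of stats::cor.
pearson_oracle <- function(a, b) {
  ma <- sum(a) / length(a)
  mb <- sum(b) / length(b)
  num <- sum((a - ma) * (b - mb))
  den <- sqrt(sum((a - ma)^2) * sum((b - mb)^2))
  num / den
}

# Brute-force sliding least-squares Savitzky-Golay oracle with
# terminal-window polynomial extrapolation at the edges.
sg_oracle <- function(x, window, order) {
  half <- (window - 1L) %/% 2L
  L <- length(x)
  out <- numeric(L)
  for (i in seq_len(L)) {
    lo <- max(1L, min(i - half, L - window + 1L))
    idx <- lo:(lo + window - 1L)
    fit <- lm.fit(outer(idx - i, 0:order, "^"), x[idx])
    out[i] <- fit$coefficients[1L]
  }
  out
}
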