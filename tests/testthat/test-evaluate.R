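test_that("pearson matches the direct product-moment formula", {
  set.seed(8)
  x <- rnorm(40)
  expect_equal(pearson(x, x), 1.0)
  expect_equal(pearson(x, -x), -1.0)
  for (i in 1:25) {
    a <- rnorm(30)
    b <- rnorm(30)
    expect_equal(pearson(a, b), pearson_oracle(a, b), tolerance = 1e-12)
  }
  # symmetry and affine invariance
  a <- rnorm(30); b <- rnorm(30)
  expect_equal(pearson(a, b), pearson(b, a), tolerance = 1e-15)
  expect_equal(pearson(3 * a + 2, b), pearson(a, b), tolerance = 1e-12)
  # undefined for constant input; shape error for mismatched lengths
  expect_true(is.na(pearson(rep(1, 10), rnorm(10))))
  expect_error(pearson(rnorm(5), rnorm(6)), "mismatch")
})

test_that("correlation_report summarizes the per-row distribution", {
  bases <- make_bases(6L)
  identical_report <- correlation_report(bases, bases)
  expect_equal(identical_report$correlations[[1L]], rep(1, 6L))
  expect_equal(identical_report$summary$mean, 1)

  set.seed(3)
  noisy <- spectrum_set(bases$axis,
                        bases$matrix + matrix(rnorm(6 * 64, 0, 0.2), 6L),
                        normalized = FALSE)
  rep2 <- correlation_report(noisy, bases, label = "noisy")
  r <- rep2$correlations$noisy
  # summary is recomputable from the per-row column
  expect_equal(rep2$summary$mean, mean(r))
  expect_equal(rep2$summary[, c("q25", "median", "q75")],
               data.frame(q25 = quantile(r, 0.25, names = FALSE),
                          median = quantile(r, 0.5, names = FALSE),
                          q75 = quantile(r, 0.75, names = FALSE)))
  expect_equal(rep2$summary$min, min(r))
  expect_equal(rep2$summary$max, max(r))

  # undefined rows are excluded with a warning, and counted
  flat <- bases
  flat$matrix[2L, ] <- 0.5
  expect_warning(rep3 <- correlation_report(flat, bases), "undefined")
  expect_equal(rep3$summary$n_undefined, 1L)
  expect_equal(rep3$summary$n, 5L)

  # misaligned sets are a shape error
  small <- spectrum_set(bases$axis, bases$matrix[1:3, ])
  expect_error(correlation_report(small, bases), "misaligned")
})

test_that("savitzky_golay equals brute-force sliding least squares", {
  set.seed(21)
  x <- cumsum(rnorm(200))
  for (case in list(c(15L, 1L), c(9L, 2L), c(21L, 3L), c(5L, 1L))) {
    expect_equal(savitzky_golay(x, case[1L], case[2L]),
                 sg_oracle(x, case[1L], case[2L]), tolerance = 1e-10)
  }
  # a first-order fit reproduces an exact line
  line <- 2 * seq_len(100) + 3
  expect_equal(savitzky_golay(line, 15L, 1L), line, tolerance = 1e-9)
  # an interpolating fit (order = window - 1) reproduces any signal
  expect_equal(savitzky_golay(x, 5L, 4L), x, tolerance = 1e-6)
  # parameter errors
  expect_error(savitzky_golay(x, 14L, 1L), "odd")
  expect_error(savitzky_golay(x, 15L, 15L), "order")
})

test_that("sg_parameter_sweep covers exactly the valid grid", {
  bases <- make_bases(4L)
  set.seed(9)
  noisy <- spectrum_set(bases$axis,
                        bases$matrix + matrix(rnorm(4 * 64, 0, 0.1), 4L))
  single <- sg_parameter_sweep(noisy, bases, windows = 15L, orders = 1L)
  expect_equal(nrow(single), 1L)

  windows <- c(5L, 9L, 15L)
  orders <- c(1L, 4L, 7L)
  grid <- sg_parameter_sweep(noisy, bases, windows = windows,
                             orders = orders)
  # row count = |windows| * |orders| - #invalid (order >= window)
  expect_equal(nrow(grid), sum(outer(orders, windows, "<")))
  # each row's mean correlation matches direct recomputation
  for (i in seq_len(nrow(grid))) {
    sm <- sg_smooth_set(noisy, grid$window[i], grid$order[i])
    direct <- mean(vapply(1:4, function(j)
      pearson(sm$matrix[j, ], bases$matrix[j, ]), 0))
    expect_equal(grid$mean_correlation[i], direct, tolerance = 1e-12)
  }
  expect_error(sg_parameter_sweep(noisy, bases, windows = integer(0)),
               "nonempty")
})

test_that("select_below_correlation applies a strict threshold", {
  # construct rows of known correlation to the target by mixing the target
  # with an orthogonalized noise component
  set.seed(33)
  L <- 128L
  target <- scale(rnorm(L))[, 1L]
  make_row <- function(rho) {
    z <- rnorm(L)
    z <- scale(z - target * sum(z * target) / sum(target^2))[, 1L]
    rho * target + sqrt(1 - rho^2) * z
  }
  rows <- rbind(make_row(0.3), make_row(0.5), make_row(0.7))
  set <- spectrum_set(seq_len(L), rows)
  targets <- spectrum_set(seq_len(L), rbind(target, target, target))
  got <- vapply(1:3, function(i) pearson(rows[i, ], target), 0)
  expect_equal(got, c(0.3, 0.5, 0.7), tolerance = 1e-9)
  # strict <: the 0.5 row is not selected at threshold 0.5
  expect_identical(select_below_correlation(set, targets, 0.5), 1L)
  # vacuous threshold selects everything
  expect_identical(select_below_correlation(set, targets, 2), 1:3)
  # brute-force scan agreement on random data
  set.seed(34)
  A <- matrix(rnorm(20 * 50), 20L)
  B <- matrix(rnorm(20 * 50), 20L)
  sA <- spectrum_set(seq_len(50L), A)
  sB <- spectrum_set(seq_len(50L), B)
  brute <- which(vapply(1:20, function(i) cor(A[i, ], B[i, ]), 0) < 0.1)
  expect_identical(select_below_correlation(sA, sB, 0.1), brute)
})

test_that("compare_methods scores both methods on identical rows", {
  # a 512-point grid keeps the 15-point window narrow relative to bands
  bases <- make_bases(5L, axis = tiny_axis(512L))
  data <- build_dataset(bases, 4L,
                        distortion_spec(noise_sigma = 0.02, seed = 6L))
  model <- ae_train(NULL, data,
                    tiny_train_config(input_width = 512L, latent_dim = 64L,
                                      epochs = 60L))
  # clean spectra passed as noisy: both methods near-perfect
  # a short cubic window barely perturbs a clean signal
  clean_as_noisy <- compare_methods(data$clean, data$clean, model,
                                    sg_window = 5L, sg_order = 3L)
  expect_length(clean_as_noisy$correlations[["autoencoder"]],
                length(clean_as_noisy$correlations[["savitzky_golay"]]))
  expect_gt(clean_as_noisy$summary$mean[
    clean_as_noisy$summary$method == "savitzky_golay"], 0.99)
  expect_identical(clean_as_noisy$n_spectra, nrow(data$clean$matrix))
})

test_that("reports export per-row CSV and summary JSON", {
  bases <- make_bases(3L)
  rep <- correlation_report(bases, bases, label = "identity")
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_report(rep, csv_path = csv, json_path = js)
  back <- utils::read.csv(csv)
  expect_equal(back$identity, rep$correlations$identity)
  summ <- jsonlite::fromJSON(js)
  expect_equal(summ$mean, 1)
})
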