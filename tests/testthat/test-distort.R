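base_x <- function(n = 256L) {
  generate_base_spectrum(4L, axis = seq(400, 4000, length.out = n),
                         seed = 3L)$intensities
}

test_that("every operator with zero amplitude or count is the identity", {
  x <- base_x()
  set.seed(1)
  expect_identical(add_noise(x, 0), x)
  expect_identical(add_baseline_bend(x, 0), x)
  expect_identical(add_ghost_peaks(x, 0L), x)
  expect_identical(add_fluorescence(x, 0), x)
  expect_identical(add_cosmic_rays(x, 0L), x)
  expect_identical(add_periodic_interference(x, 0, 50), x)
})

test_that("operators preserve the signal length", {
  for (n in c(33L, 256L, 1024L)) {
    x <- base_x(n)
    set.seed(2)
    expect_length(add_noise(x, 0.1, 0.5), n)
    expect_length(add_baseline_bend(x, 0.3), n)
    expect_length(add_ghost_peaks(x, 2L), n)
    expect_length(add_fluorescence(x, 0.8), n)
    expect_length(add_cosmic_rays(x, 2L), n)
    expect_length(add_periodic_interference(x, 0.2, 40), n)
  }
})

test_that("add_noise matches its nominal moments and the sqrt(n) law", {
  x <- numeric(1e5)
  set.seed(10)
  eps <- add_noise(x, 0.05) - x
  expect_equal(sd(eps), 0.05, tolerance = 0.05)
  expect_lt(abs(mean(eps)), 0.001)

  # averaging n = 4 independent noisy copies halves the residual std
  set.seed(11)
  draws <- replicate(4L, add_noise(x, 0.05))
  avg <- rowMeans(draws)
  expect_equal(sd(avg - x), 0.05 / sqrt(4), tolerance = 0.05)

  # ramp: noise std grows linearly along the axis
  set.seed(12)
  ramped <- add_noise(numeric(2e5), 0.05, ramp = 1)
  first <- sd(ramped[1:2e4])          # sigma ~ 0.05 at the start
  last <- sd(ramped[(1.8e5):2e5])     # sigma ~ 0.10 at the end
  expect_equal(last / first, 2, tolerance = 0.1)
})

test_that("baseline bend is the seeded polynomial, bounded by amp", {
  x <- base_x()
  set.seed(20)
  out <- add_baseline_bend(x, 0.4)
  # regenerating under the same seed reproduces the polynomial exactly
  set.seed(20)
  out2 <- add_baseline_bend(x, 0.4)
  expect_identical(out, out2)
  # the bend is a degree-<=4 polynomial in the axis parameterization:
  # a quartic fit to (out - x) must be exact
  t <- seq(-1, 1, length.out = length(x))
  fit <- lm.fit(outer(t, 0:4, "^"), out - x)
  expect_lt(max(abs(fit$residuals)), 1e-9)
  # max excursion equals amp over many seeds
  for (s in 1:100) {
    set.seed(s)
    d <- add_baseline_bend(x, 0.25) - x
    expect_lt(max(abs(d)), 0.25 + 1e-9)
  }
})

test_that("ghost peaks are nonnegative additive bands of the right count", {
  x <- base_x(1024L)
  set.seed(30)
  out <- add_ghost_peaks(x, 3L)
  d <- out - x
  expect_true(all(d >= -1e-12))
  # reproducibility under a fixed seed
  set.seed(30)
  expect_identical(add_ghost_peaks(x, 3L), out)
  # on a flat signal with well-separated draws the added bands give
  # exactly `count` local maxima above half-height
  found <- 0L
  for (s in 1:50) {
    set.seed(s)
    d0 <- add_ghost_peaks(numeric(1024L), 3L)
    peaks <- which(diff(sign(diff(d0))) == -2) + 1L
    peaks <- peaks[d0[peaks] > max(d0) / 2]
    # count only when all three bands are cleanly separated (no overlap
    # merging two draws into one mode)
    if (length(peaks) == 3L) found <- found + 1L
  }
  expect_gte(found, 20L)  # separation holds for most random placements
})

test_that("fluorescence hump is unimodal, broad, with height exactly amp", {
  for (s in 1:100) {
    set.seed(s)
    d <- add_fluorescence(numeric(512L), 0.7)
    expect_equal(max(d), 0.7, tolerance = 1e-9)
    # unimodal: intensity rises to one argmax then falls
    peak <- which.max(d)
    expect_true(all(diff(d[seq_len(peak)]) >= -1e-12))
    expect_true(all(diff(d[peak:length(d)]) <= 1e-12))
    # FWHM (within the observed window) exceeds 25% of the axis span
    above <- range(which(d >= 0.35))
    # when the half-height region is clipped by the window edge the visible
    # width is a lower bound on the true FWHM only if clipped on one side
    width <- above[2] - above[1] + 1L
    touches_edge <- above[1] == 1L || above[2] == 512L
    if (!touches_edge) expect_gt(width, 0.25 * 512)
  }
})

test_that("cosmic rays are disjoint spikes <= 3 bins with bounded heights", {
  x <- numeric(600L)
  for (s in 1:100) {
    set.seed(s)
    d <- add_cosmic_rays(x, 4L, c(0.3, 0.9))
    runs <- rle(d > 0)
    spike_runs <- which(runs$values)
    expect_identical(length(spike_runs), 4L)
    expect_true(all(runs$lengths[spike_runs] <= 3L))
    # per-run peak heights stay within the requested range
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (r in spike_runs) {
      h <- max(d[starts[r]:ends[r]])
      expect_gte(h, 0.3)
      expect_lte(h, 0.9)
    }
  }
  expect_error(add_cosmic_rays(numeric(10L), 5L), "cannot place")
})

test_that("periodic interference has the requested dominant frequency", {
  L <- 1024L
  period <- 64
  set.seed(40)
  d <- add_periodic_interference(numeric(L), 0.5, period)
  expect_lte(max(abs(d)), 0.5)
  spec <- Mod(stats::fft(d))[2:(L / 2)]
  dominant_bin <- which.max(spec) + 1L  # fft bin k+1 <-> frequency k/L
  expect_equal((dominant_bin - 1) / L, 1 / period, tolerance = 1 / L)
})

test_that("generate_base_spectrum is seeded, nonnegative, vocabulary-based", {
  axis <- tiny_axis(256L)
  # empty sum
  expect_equal(generate_base_spectrum(0L, axis)$intensities,
               numeric(256L))
  # a single Gaussian at a forced center peaks in that center's bin
  center <- axis[100L]
  s <- generate_base_spectrum(1L, axis, seed = 5L, centers = center,
                              widths = 50, heights = 1)
  expect_identical(which.max(s$intensities), 100L)
  # determinism: same seed, same spectrum; different seed, different
  a <- generate_base_spectrum(5L, axis, seed = 9L)
  b <- generate_base_spectrum(5L, axis, seed = 9L)
  c <- generate_base_spectrum(5L, axis, seed = 10L)
  expect_identical(a$intensities, b$intensities)
  expect_false(identical(a$intensities, c$intensities))
  expect_true(all(a$intensities >= 0))
})

test_that("build_dataset pairs rows, normalizes, and reproduces bit-for-bit", {
  bases <- make_bases(3L, axis = tiny_axis(128L))
  spec <- distortion_spec(noise_sigma = c(0.05, 0.2), baseline_amp = 0.3,
                          cosmic_count = 1L, seed = 77L)
  ds <- build_dataset(bases, 4L, spec)
  expect_s3_class(ds, "paired_dataset")
  expect_equal(dim(ds$noisy$matrix), c(12L, 128L))
  expect_equal(dim(ds$clean$matrix), dim(ds$noisy$matrix))
  expect_identical(ds$base_index, rep(1:3, each = 4L))
  # all entries within [0,1]
  expect_true(all(ds$noisy$matrix >= 0 & ds$noisy$matrix <= 1))
  expect_true(all(ds$clean$matrix >= 0 & ds$clean$matrix <= 1))
  # clean rows are the normalized bases, row-aligned with noisy
  expect_equal(ds$clean$matrix, bases$matrix[ds$base_index, ])
  # bit-for-bit reproducibility under the spec seed
  ds2 <- build_dataset(bases, 4L, spec)
  expect_identical(ds$noisy$matrix, ds2$noisy$matrix)

  # all-zero distortion spec gives noisy == clean
  idspec <- distortion_spec(noise_sigma = 0, seed = 1L)
  dsid <- build_dataset(bases, 1L, idspec)
  expect_equal(dsid$noisy$matrix, dsid$clean$matrix, tolerance = 1e-12)
})

test_that("paired datasets and distortion specs round-trip to disk", {
  bases <- make_bases(2L, axis = tiny_axis(32L))
  ds <- build_dataset(bases, 2L, distortion_spec(seed = 3L))
  stem <- file.path(withr::local_tempdir(), "ds")
  save_dataset(ds, stem)
  back <- load_dataset(stem)
  expect_equal(back$noisy$matrix, ds$noisy$matrix, tolerance = 1e-12)
  expect_equal(back$clean$matrix, ds$clean$matrix, tolerance = 1e-12)
  expect_identical(back$base_index, ds$base_index)

  spec <- distortion_spec(noise_sigma = 0.1, ghost_peak_count = 2L,
                          seed = 9L)
  for (ext in c(".json", ".yml")) {
    p <- withr::local_tempfile(fileext = ext)
    write_distortion_spec(spec, p)
    expect_equal(unclass(read_distortion_spec(p)), unclass(spec))
  }
})
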