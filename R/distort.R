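#' Distortion parameter bundle
#'
#' Collects the parameters of all six artifact operators plus the RNG seed
#' that makes a dataset build reproducible. Amplitudes are on the 0-1
#' normalized-intensity scale. An operator whose amplitude (or count) is zero
#' is skipped entirely, so the all-zero spec is the identity pipeline.
#'
#' @param noise_sigma Gaussian noise std; a scalar, or a `(lo, hi)` range
#'   from which a per-spectrum sigma is drawn uniformly. Default
#'   `c(0.01, 0.15)`.
#' @param noise_ramp Multiplicative slope of sigma across the axis (>= 0);
#'   `ramp > 0` emulates CCD Raman detectors whose noise grows toward high
#'   wavenumbers.
#' @param baseline_amp Maximum excursion of the random low-order polynomial
#'   baseline bend.
#' @param ghost_peak_count Number of spurious additive bands per spectrum.
#' @param fluorescence_amp Height of the broad fluorescence hump.
#' @param cosmic_count Number of narrow cosmic-ray spikes.
#' @param cosmic_height_range `(lo, hi)` spike heights.
#' @param interference_amp,interference_period Sinusoidal baseline
#'   oscillation amplitude and period (in axis bins).
#' @param seed Integer RNG seed for the dataset build.
#' @return An object of class `distortion_spec`.
#' @export
distortion_spec <- function(noise_sigma = c(0.01, 0.15), noise_ramp = 0,
                            baseline_amp = 0, ghost_peak_count = 0L,
                            fluorescence_amp = 0, cosmic_count = 0L,
                            cosmic_height_range = c(0.3, 1.0),
                            interference_amp = 0, interference_period = 100,
                            seed = 1L) {
  if (!length(noise_sigma) %in% c(1L, 2L) || any(noise_sigma < 0)) {
    stop("noise_sigma must be a nonnegative scalar or (lo, hi) range",
         call. = FALSE)
  }
  if (length(noise_sigma) == 2L && noise_sigma[1L] > noise_sigma[2L]) {
    stop("noise_sigma range must have lo <= hi", call. = FALSE)
  }
  stopifnot(noise_ramp >= 0, baseline_amp >= 0, ghost_peak_count >= 0,
            fluorescence_amp >= 0, cosmic_count >= 0,
            length(cosmic_height_range) == 2L,
            cosmic_height_range[1L] <= cosmic_height_range[2L],
            interference_amp >= 0, interference_period > 0)
  structure(
    list(noise_sigma = as.numeric(noise_sigma),
         noise_ramp = as.numeric(noise_ramp),
         baseline_amp = as.numeric(baseline_amp),
         ghost_peak_count = as.integer(ghost_peak_count),
         fluorescence_amp = as.numeric(fluorescence_amp),
         cosmic_count = as.integer(cosmic_count),
         cosmic_height_range = as.numeric(cosmic_height_range),
         interference_amp = as.numeric(interference_amp),
         interference_period = as.numeric(interference_period),
         seed = as.integer(seed)),
    class = "distortion_spec"
  )
}

#' Serialize / restore a distortion spec as JSON or YAML
#' @param spec A `distortion_spec`.
#' @param path Output (or input) path; extension `.json` or `.yml`/`.yaml`
#'   selects the format.
#' @return `write_distortion_spec` returns `path` invisibly;
#'   `read_distortion_spec` the restored spec.
#' @export
write_distortion_spec <- function(spec, path) {
  stopifnot(inherits(spec, "distortion_spec"))
  fields <- unclass(spec)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(fields, path)
  } else {
    jsonlite::write_json(fields, path, auto_unbox = FALSE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_distortion_spec
#' @export
read_distortion_spec <- function(path) {
  fields <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
    else jsonlite::fromJSON(path)
  do.call(distortion_spec, fields)
}

#' Characteristic band vocabulary for synthetic spectra
#'
#' Vibrational spectra of related compounds (e.g. the polymers of a
#' reference library) share characteristic group frequencies: different
#' materials light up different subsets of largely the same band positions.
#' The vocabulary is a deterministic function of the axis: `n_bands`
#' candidate centers spread over the inner axis range, each with a
#' characteristic width between 0.4% and 1.5% of the span.
#'
#' @param axis Wavenumber grid.
#' @param n_bands Vocabulary size (default 36).
#' @return data.frame with columns `center` and `width`.
#' @export
band_vocabulary <- function(axis, n_bands = 36L) {
  old <- local_seed(7241L)
  on.exit(restore_seed(old))
  span <- max(axis) - min(axis)
  data.frame(
    center = stats::runif(n_bands, min(axis) + 0.02 * span,
                          max(axis) - 0.02 * span),
    width = stats::runif(n_bands, 0.004, 0.015) * span
  )
}

#' Generate a synthetic clean base spectrum
#'
#' Sums `n_peaks` Gaussian or Lorentzian bands whose centers are drawn
#' (without replacement, with small position jitter) from the shared
#' [band_vocabulary()] of the axis, with randomized widths and heights.
#' Sampling from a common band vocabulary mimics how the members of a real
#' reference library share functional-group frequencies while differing in
#' which bands are present and how strong they are; it is what makes
#' reconstruction of held-out library spectra a learnable problem. These
#' peak-mixture spectra stand in for a measured attenuated-total-reflection
#' (ATR) reference library as reconstruction targets.
#'
#' @param n_peaks Number of bands (>= 0); 0 gives the flat zero spectrum.
#' @param axis Wavenumber grid (default [default_axis()]).
#' @param seed Integer seed; the same seed reproduces the same spectrum.
#' @param label Spectrum label.
#' @param centers,widths,heights Optional explicit band parameters (numeric
#'   vectors of length `n_peaks`) overriding the randomized draw; useful for
#'   constructing spectra with known peak locations.
#' @return A nonnegative [new_spectrum()].
#' @export
generate_base_spectrum <- function(n_peaks, axis = default_axis(),
                                   seed = 1L, label = NULL,
                                   centers = NULL, widths = NULL,
                                   heights = NULL) {
  stopifnot(n_peaks >= 0)
  n_peaks <- as.integer(n_peaks)
  if (is.null(label)) label <- paste0("base_", seed)
  y <- numeric(length(axis))
  if (n_peaks > 0L) {
    old <- local_seed(seed)
    on.exit(restore_seed(old))
    span <- max(axis) - min(axis)
    vocab <- band_vocabulary(axis)
    picks <- sample.int(nrow(vocab), n_peaks,
                        replace = n_peaks > nrow(vocab))
    for (p in seq_len(n_peaks)) {
      center <- if (!is.null(centers)) centers[p] else
        vocab$center[picks[p]] + stats::rnorm(1, 0, 0.002 * span)
      width <- if (!is.null(widths)) widths[p] else
        vocab$width[picks[p]] * stats::runif(1, 0.8, 1.25)
      height <- if (!is.null(heights)) heights[p] else
        stats::runif(1, 0.2, 1)
      lorentzian <- stats::runif(1) < 0.5
      y <- y + if (lorentzian) {
        height / (1 + ((axis - center) / width)^2)
      } else {
        height * exp(-0.5 * ((axis - center) / width)^2)
      }
    }
  }
  new_spectrum(axis, y, label = label)
}

# Seed scoping: stash the caller's RNG state, seed, and restore afterwards so
# seeded helpers do not perturb the global stream.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# Per-row substream seed: mixes the dataset seed with the row index; kept in
# [0, 2^31) because R seeds are 32-bit integers.
derive_row_seed <- function(seed, row) {
  as.integer((as.double(seed) * 2654435761 + as.double(row)) %% 2^31)
}

#' Add Gaussian noise, optionally ramped along the axis
#'
#' Adds `eps_i ~ Normal(0, sigma * (1 + ramp * i/(L-1)))` (i = 0..L-1) to the
#' intensity vector. `ramp > 0` gives noise increasing toward high
#' wavenumbers, as on CCD Raman detectors.
#'
#' @param x Intensity vector.
#' @param sigma Base noise std (>= 0); 0 is the identity.
#' @param ramp Slope of sigma across the axis (>= 0).
#' @return Distorted vector of the same length. Uses the current RNG stream.
#' @export
add_noise <- function(x, sigma, ramp = 0) {
  stopifnot(sigma >= 0, ramp >= 0)
  if (sigma == 0) return(x)
  L <- length(x)
  sd_i <- sigma * (1 + ramp * (seq_len(L) - 1) / (L - 1))
  x + stats::rnorm(L, 0, sd_i)
}

#' Add a smooth random baseline bend
#'
#' Adds a random polynomial of degree <= 4 (coefficients standard normal,
#' evaluated on a -1..1 parameterization of the axis) rescaled so its maximum
#' absolute excursion equals `amp`.
#'
#' @param x Intensity vector.
#' @param amp Maximum baseline excursion (>= 0); 0 is the identity.
#' @return Distorted vector. Uses the current RNG stream.
#' @export
add_baseline_bend <- function(x, amp) {
  stopifnot(amp >= 0)
  if (amp == 0) return(x)
  L <- length(x)
  t <- seq(-1, 1, length.out = L)
  coef <- stats::rnorm(5L)
  poly <- coef[1L] + coef[2L] * t + coef[3L] * t^2 + coef[4L] * t^3 +
    coef[5L] * t^4
  peak <- max(abs(poly))
  if (peak == 0) return(x)
  x + poly * (amp / peak)
}

#' Add spurious ghost peaks
#'
#' Adds `count` positive Gaussian bands at random positions with band-like
#' widths (sigma 0.5-2% of the axis length: wider than cosmic spikes,
#' narrower than a fluorescence hump) and heights uniform in 0.1-0.5.
#'
#' @param x Intensity vector.
#' @param count Number of ghost bands (>= 0); 0 is the identity.
#' @return Distorted vector, `(out - in) >= 0` everywhere. Uses the current
#'   RNG stream.
#' @export
add_ghost_peaks <- function(x, count) {
  stopifnot(count >= 0)
  count <- as.integer(count)
  if (count == 0L) return(x)
  L <- length(x)
  i <- seq_len(L)
  for (p in seq_len(count)) {
    center <- stats::runif(1, 1, L)
    width <- stats::runif(1, 0.005, 0.02) * L
    height <- stats::runif(1, 0.1, 0.5)
    x <- x + height * exp(-0.5 * ((i - center) / width)^2)
  }
  x
}

#' Add a broad fluorescence hump
#'
#' Adds a single broad unimodal Gaussian background of height exactly `amp`
#' (peak over the sampled grid). The width is drawn so the full width at
#' half maximum always exceeds 25% of the axis span, as real fluorescence
#' backgrounds dwarf individual Raman bands in width.
#'
#' @param x Intensity vector.
#' @param amp Hump height (>= 0); 0 is the identity.
#' @return Distorted vector. Uses the current RNG stream.
#' @export
add_fluorescence <- function(x, amp) {
  stopifnot(amp >= 0)
  if (amp == 0) return(x)
  L <- length(x)
  i <- seq_len(L)
  center <- stats::runif(1, 1, L)
  # FWHM = 2*sqrt(2*log(2))*sigma ~ 2.355*sigma; sigma >= 0.12*L keeps
  # FWHM > 0.28*L.
  width <- stats::runif(1, 0.12, 0.30) * L
  hump <- exp(-0.5 * ((i - center) / width)^2)
  x + amp * hump / max(hump)
}

#' Add narrow cosmic-ray spikes
#'
#' Adds `count` disjoint spikes, each at most 3 bins wide: a central bin at a
#' height drawn uniformly from `height_range`, flanked (for 2- and 3-bin
#' spikes) by shoulders at random fractions of that height. Spike footprints
#' never touch, so `(out - in) > 0` falls into exactly `count` runs.
#'
#' @param x Intensity vector.
#' @param count Number of spikes (>= 0); 0 is the identity.
#' @param height_range `(lo, hi)` peak heights, `0 < lo <= hi`.
#' @return Distorted vector. Uses the current RNG stream.
#' @export
add_cosmic_rays <- function(x, count, height_range = c(0.3, 1.0)) {
  stopifnot(count >= 0, length(height_range) == 2L,
            height_range[1L] > 0, height_range[1L] <= height_range[2L])
  count <- as.integer(count)
  if (count == 0L) return(x)
  L <- length(x)
  # Each spike occupies <= 3 bins plus a 1-bin separating gap on each side.
  if (count * 5L > L) {
    stop("cannot place ", count, " disjoint cosmic spikes on ", L, " bins",
         call. = FALSE)
  }
  centers <- integer(0)
  attempts <- 0L
  while (length(centers) < count) {
    cand <- sample.int(L - 3L, 1L) + 1L  # keep 3-bin footprint inside axis
    if (all(abs(cand - centers) > 4L)) centers <- c(centers, cand)
    attempts <- attempts + 1L
    if (attempts > 1000L * count) {
      stop("failed to place ", count, " disjoint cosmic spikes", call. = FALSE)
    }
  }
  for (c0 in centers) {
    h <- stats::runif(1, height_range[1L], height_range[2L])
    w <- sample.int(3L, 1L)  # 1, 2 or 3 bins
    x[c0] <- x[c0] + h
    if (w >= 2L) x[c0 + 1L] <- x[c0 + 1L] + h * stats::runif(1, 0.2, 0.8)
    if (w == 3L) x[c0 - 1L] <- x[c0 - 1L] + h * stats::runif(1, 0.2, 0.8)
  }
  x
}

#' Add a periodic interference pattern
#'
#' Adds `amp * sin(2*pi*i/period + phi)` with random phase `phi`, emulating
#' the sinusoidal baseline oscillation produced by thin-film interference,
#' which conventional baseline algorithms mistake for broad bands.
#'
#' @param x Intensity vector.
#' @param amp Oscillation amplitude (>= 0); 0 is the identity.
#' @param period Oscillation period in bins (> 0).
#' @return Distorted vector. Uses the current RNG stream.
#' @export
add_periodic_interference <- function(x, amp, period) {
  stopifnot(amp >= 0, period > 0)
  if (amp == 0) return(x)
  L <- length(x)
  phi <- stats::runif(1, 0, 2 * pi)
  x + amp * sin(2 * pi * (seq_len(L) - 1) / period + phi)
}

# Apply the full operator chain of `spec` to one raw intensity row.
# Order is fixed: noise -> baseline -> ghost -> fluorescence -> cosmic ->
# interference. Assumes the caller has seeded the RNG for this row.
apply_distortions <- function(x, spec) {
  sigma <- if (length(spec$noise_sigma) == 2L) {
    stats::runif(1, spec$noise_sigma[1L], spec$noise_sigma[2L])
  } else spec$noise_sigma
  x <- add_noise(x, sigma, spec$noise_ramp)
  x <- add_baseline_bend(x, spec$baseline_amp)
  x <- add_ghost_peaks(x, spec$ghost_peak_count)
  x <- add_fluorescence(x, spec$fluorescence_amp)
  x <- add_cosmic_rays(x, spec$cosmic_count, spec$cosmic_height_range)
  add_periodic_interference(x, spec$interference_amp, spec$interference_period)
}

#' Build a paired (noisy, clean) training dataset
#'
#' Every base spectrum is min-max normalized and replicated `n_variations`
#' times; each replicate is distorted by the operator chain of `spec` and
#' then re-normalized to 0-1 (network inputs must span 0-1 regardless of
#' artifact magnitude). Row i of the noisy matrix is aligned with row i of
#' the clean matrix, and `base_index` records which base produced each row.
#' The build is bit-reproducible under `spec$seed`: each row draws from its
#' own substream derived from the seed and the row index.
#'
#' @param bases A `spectrum_set` of clean base spectra on the common axis.
#' @param n_variations Distorted replicates per base (>= 1).
#' @param spec A [distortion_spec()].
#' @return An object of class `paired_dataset`: list with `noisy` and
#'   `clean` (`spectrum_set`s of identical shape) and integer `base_index`.
#' @export
build_dataset <- function(bases, n_variations, spec) {
  stopifnot(inherits(bases, "spectrum_set"), inherits(spec, "distortion_spec"),
            n_variations >= 1)
  n_b <- n_spectra(bases)
  if (n_b == 0L) stop("bases must be nonempty", call. = FALSE)
  n_variations <- as.integer(n_variations)
  L <- length(bases$axis)
  clean_bases <- if (bases$normalized) bases else normalize_set(bases)

  n_rows <- n_b * n_variations
  noisy <- base::matrix(0, n_rows, L)
  clean <- base::matrix(0, n_rows, L)
  degen <- logical(n_rows)
  base_index <- integer(n_rows)
  labels <- character(n_rows)

  old <- local_seed(spec$seed)
  on.exit(restore_seed(old))
  row <- 0L
  for (b in seq_len(n_b)) {
    base_row <- clean_bases$matrix[b, ]
    for (v in seq_len(n_variations)) {
      row <- row + 1L
      set.seed(derive_row_seed(spec$seed, row))
      distorted <- apply_distortions(base_row, spec)
      sc <- normalize_minmax_vec(distorted)
      noisy[row, ] <- sc$x
      degen[row] <- sc$degenerate
      clean[row, ] <- base_row
      base_index[row] <- b
      labels[row] <- sprintf("%s_v%d", clean_bases$labels[b], v)
    }
  }
  structure(
    list(
      noisy = spectrum_set(bases$axis, noisy, labels = labels,
                           normalized = TRUE, degenerate = degen),
      clean = spectrum_set(bases$axis, clean, labels = labels,
                           normalized = TRUE,
                           degenerate = clean_bases$degenerate[base_index]),
      base_index = base_index
    ),
    class = "paired_dataset"
  )
}

#' @export
print.paired_dataset <- function(x, ...) {
  cat(sprintf("<paired_dataset: %d rows x %d wavenumbers, %d bases>\n",
              nrow(x$noisy$matrix), length(x$noisy$axis),
              length(unique(x$base_index))))
  invisible(x)
}

#' Save / load a paired dataset
#'
#' Persists the noisy and clean sets with [save_set()] plus a JSON sidecar
#' holding `base_index`.
#'
#' @param ds A `paired_dataset`.
#' @param stem Path stem; writes `<stem>.noisy.tsv`, `<stem>.clean.tsv`,
#'   `<stem>.meta.json`.
#' @return `save_dataset` returns `stem` invisibly; `load_dataset` the
#'   restored dataset.
#' @export
save_dataset <- function(ds, stem) {
  stopifnot(inherits(ds, "paired_dataset"))
  save_set(ds$noisy, paste0(stem, ".noisy.tsv"))
  save_set(ds$clean, paste0(stem, ".clean.tsv"))
  jsonlite::write_json(list(base_index = ds$base_index),
                       paste0(stem, ".meta.json"))
  invisible(stem)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(stem) {
  meta <- jsonlite::fromJSON(paste0(stem, ".meta.json"))
  structure(
    list(noisy = load_set(paste0(stem, ".noisy.tsv")),
         clean = load_set(paste0(stem, ".clean.tsv")),
         base_index = as.integer(meta$base_index)),
    class = "paired_dataset"
  )
}
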