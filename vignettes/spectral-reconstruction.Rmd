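---
title: "Autoencoder reconstruction of distorted vibrational spectra: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Autoencoder reconstruction of distorted vibrational spectra: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(specmend)
```

## The model

`specmend` reconstructs one-dimensional vibrational (FTIR/Raman) spectra
from heavily distorted measurements. All spectra are resampled onto a
shared wavenumber axis of 1024 points and min–max normalized to the 0–1
range. The reconstruction network is intentionally shallow: a densely
connected encoder maps the 1024-point input to a 128-dimensional latent
code, and a dense decoder expands back to 1024 points,

$$\hat{x} = \sigma\!\big(W_2\,\mathrm{ReLU}(W_1 x + b_1) + b_2\big),$$

with a logistic sigmoid output stage so reconstructions always lie in the
normalized intensity range. The network is trained on *pairs*: distorted
spectra on the input side, the corresponding clean spectra as targets, so
the bottleneck learns to encode only the information consistent with a
clean spectrum and to discard noise, baselines, spikes, fluorescence, and
interference in one pass. One hidden layer keeps the number of
hyperparameters low and training times in the minutes range on a single
CPU core.

Assumptions worth stating explicitly:

* the spectra to be reconstructed must come from the same "library" of
  material types the network was trained on — the model has *a priori*
  knowledge and cannot be tuned per spectrum;
* inputs must be on the training axis and 0–1 normalized (the package
  resamples and normalizes for you);
* reconstruction quality is judged by the Pearson correlation to the known
  clean target, so it measures band positions and relative intensities,
  not absolute scale.

## Training procedure and tunable parameters

`train_config()` collects the knobs. Defaults, units, and rationale:

| parameter | default | meaning |
|---|---|---|
| `input_width` | 1024 | points on the shared wavenumber axis |
| `latent_dim` | 128 | bottleneck width |
| `dropout_rate` | 0.15 | two inverted-dropout stages (after input, after latent); 0 disables |
| `loss` | MSE | canonical reconstruction loss |
| `learning_rate` | 1e-3 | Adam step size |
| `batch_size` | 32 | minibatch rows |
| `validation_split` | 0.1 | held-out fraction for early stopping |
| `early_stop_patience` | 10 | epochs without validation improvement |

The optimizer is Adam; the learning rate is halved whenever the validation
loss stalls for five consecutive epochs (floor 1e-5), and the weights of
the best validation epoch are restored at the end. Neither the loss, the
optimizer, nor the activations are forced by the scientific setting; MSE +
Adam + ReLU/sigmoid is the canonical choice for a bounded reconstruction
problem, and all of it is configurable. With a fixed `seed` training is
bit-reproducible: weight initialization, the train/validation split, epoch
shuffling, and dropout masks all derive from it.

Dropout is a regularizer against overfitting, not a general improvement:
on the denoising benchmark (no overfitting pressure, training and
validation losses track each other) it merely deletes 15% of the input
points per batch and costs reconstruction precision, so the shipped
benchmark configuration disables it. It earns its place when training data
are scarce relative to model capacity.

## The synthetic data generator

No measured reference library is bundled, so the package generates one.
`generate_base_spectrum()` sums 3–12 Gaussian/Lorentzian bands whose
centers are drawn from a shared **band vocabulary** — 36 candidate
positions with characteristic widths (0.4–1.5% of the axis span), fixed
deterministically per axis — with small per-spectrum position jitter and
random heights. This mirrors the structure of a real reference library:
related materials share functional-group frequencies and differ in which
bands are present and how strong they are. That shared structure is not a
convenience; it is the precondition for the method. A network can only
reconstruct held-out spectra if they are new *combinations* of features it
has seen. (With peak positions drawn uniformly over the axis instead,
every held-out spectrum is out-of-distribution and no training-set size
rescues reconstruction — a useful negative control, not a usable fixture.)

The six distortion operators are applied in a fixed order (noise →
baseline bend → ghost peaks → fluorescence → cosmic rays → periodic
interference), then the distorted row is re-normalized to 0–1 — network
inputs must span the unit range regardless of artifact magnitude. The
clean target row is the normalized base spectrum. Operator defaults (all
on the 0–1 intensity scale): noise sigma drawn per spectrum from
0.01–0.15, with an optional linear ramp along the axis emulating
CCD-detector noise growth toward high wavenumbers; baseline bends are
random degree-≤4 polynomials scaled to an exact maximum excursion;
fluorescence is a single Gaussian hump with FWHM above 25% of the axis
span; cosmic spikes are ≤3 bins wide and mutually disjoint; interference
is a pure sinusoid with random phase. Every operator at zero
amplitude/count is the identity, and a dataset build is bit-reproducible
from its seed (each row uses a substream derived from seed and row index).

What the generator does **not** emulate: Mie-scattering band distortions
(partially inverted band shapes on small particles), detector saturation,
water-vapor/CO₂ lines, wavenumber miscalibration, and the long-tailed
label noise of real libraries. Passing benchmarks on this generator
therefore shows the method works *when the training family covers the
test family* — it does not certify performance on any particular
instrument's data.

## Shipped benchmark scenarios

Three end-to-end studies are shipped with fixed default configurations
(problem sizes chosen once for single-CPU desk-scale runs; all are
config-overridable):

* **Denoising benchmark** (`run_denoise_benchmark()`): 400 training bases
  × 20 noise variations (8000 pairs), 20 held-out bases × 50 variations
  (1000 test rows); noise sigma uniform in 0.05–0.6. The upper end is
  deliberately severe — spectra on which a window smoother's output is
  itself still unrecognizable — because that is the regime that separates
  a learned reconstruction prior from local smoothing. The comparator is
  Savitzky–Golay with window 15, order 1 (the best simple setting per the
  included `sg_parameter_sweep()`). The synthetic library uses more
  training bases than a measured-library study would (hundreds instead of
  ~90) because vocabulary subsets are sampled more diversely than real
  polymer classes; coverage of band combinations, not raw row count, is
  what drives generalization here.
* **Mismatch experiment** (`run_mismatch_experiment()`): trains on mild
  noise only (sigma 0.01–0.10) and evaluates the same held-out bases under
  (a) the training family and (b) a family that additionally carries a
  full-height fluorescence hump and periodic interference. The drop in
  mean correlation quantifies how hard an unsuitable training set fails —
  the package's synthetic mirror of applying a library-trained network to
  real particle spectra.
* **Confidence study** (`run_confidence_study()`): 80 × 100 training
  encodings (8000) and 20 × 100 test encodings (2000), combined
  10000 × 128 matrix for the PCA diagnostic; per-test-spectrum mean
  Euclidean distance to the k = 5 nearest training encodings, paired with
  that spectrum's reconstruction correlation. The Spearman rank
  correlation of the pairing is negative: quality decays with distance
  from the training data. The shipped scenario uses the *mild* distortion
  family (noise sigma 0.01–0.15 plus baseline bends), and the choice
  matters: the distance screen detects base-spectrum novelty, not
  distortion severity. Under severe noise a drowned test spectrum encodes
  close to equally drowned training encodings — a small distance paired
  with a poor reconstruction — and the trend washes out or even inverts.
  The relation is deliberately reported as a rank correlation and a
  direction, not a calibrated score — it is weak, and the distance is a
  screen for extrapolation, not a confidence probability.

## Numerical choices and degenerate inputs

* Resampling is linear interpolation with edge clamping — order-preserving,
  artifact-free, standard chemometrics practice; the axis endpoints of the
  default 1024-point grid span 400–4000 cm⁻¹ (configurable).
* Flat (constant) spectra min–max-normalize to all zeros and carry a
  `degenerate` flag instead of raising, so batch jobs never abort; such
  rows are likewise excluded (and counted) from correlation summaries,
  because the Pearson correlation of a constant vector is undefined and
  imputing it would bias means.
* The Savitzky–Golay filter handles edges by evaluating the polynomial
  fitted to the terminal windows (verified against a brute-force sliding
  least-squares oracle to ~1e-14).
* Latent distances are plain Euclidean in the raw 128-dimensional code
  space — no whitening or scaling, the simplest defensible reading of a
  "distance in the encoded space". The acceptance threshold is mandatory
  user input; no default is shipped because a useful bound depends
  entirely on the training data's distance scale.
* The confidence PCA is fitted on the *combined* train+test encodings.
  That leaks test structure into the axes and would be wrong for an
  estimator; it is accepted here because the projection is a diagnostic
  visualization only.
* Ties in kNN distances need no special handling (distances enter a mean);
  PCA component signs are arbitrary and tests compare up to sign.

## Known limitations

* The network cannot beat its training set: the mismatch experiment shows
  mean correlations collapsing when artifact families differ. Retraining
  on representative data is the only fix.
* A reconstruction always *looks* clean; failures move bands rather than
  leaving noise. Use the latent-distance screen, and treat accepted
  reconstructions as hypotheses for library matching, not ground truth.
* The latent-distance/quality relation is weak (negative in rank, far from
  a calibrated confidence); spectra close to their target can reconstruct
  well even at a large latent distance.
* Training is full-batch-in-memory; datasets of hundreds of thousands of
  rows would need chunked training, which the package does not implement.
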