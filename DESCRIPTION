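Package: specmend
Title: Autoencoder Reconstruction of Distorted FTIR and Raman Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Removes noise, baseline bending, ghost peaks, fluorescence
    backgrounds, cosmic-ray spikes, and periodic interference from
    one-dimensional vibrational (FTIR/Raman) spectra using a shallow dense
    denoising autoencoder. Ships the synthetic artifact generators used to
    build paired training data, a Savitzky-Golay comparator, Pearson
    correlation scoring of reconstructions, and a latent-space
    k-nearest-neighbour confidence screen for rejecting untrustworthy
    reconstructions. Aimed at batch processing of micro-FTIR and micro-Raman
    particle spectra in environmental microplastics monitoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    signal,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
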