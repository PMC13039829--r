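Package: retquant
Title: Quantification Pipelines for Retinal Degeneration Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-based and proteomic quantification machinery for studies of
    photoreceptor degeneration. Provides seeded synthetic-data generators with
    exact ground truth (layered retinal section phantoms with bipolar-cell
    dendritic sprouts, electron-microscopy terminal/mitochondria phantoms,
    electroretinogram waveforms, overdispersed spectral-count matrices);
    confocal quantification (maximum projection, retinal layer masks,
    dendritic-sprouting length and density via skeletonization,
    compartmental intensities, TUNEL counts, ONL thickness); terminal and
    mitochondrial morphometry; ERG a-/b-wave feature extraction including a
    reference-implicit-time rule for traces lacking a b-wave peak; and a
    label-free spectral-counting differential-expression procedure combining
    a signal-to-noise (SAM-type) weight, a one-tail unequal-variance t-test
    and an empirically calibrated fold-change window, with set comparison and
    hypergeometric gene-set over-representation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    fgsea,
    jsonlite,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
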