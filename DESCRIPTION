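Package: hyperleaf
Title: Hyperspectral and Infrared Spectroscopy of Leaf Stress with an
    Attention-Gated Recurrent Classifier
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for detecting abiotic stress in plant leaves from
    visible/near-infrared (VNIR) hyperspectral imagery and Fourier-transform
    infrared (FTIR) microspectroscopy.  Covers the full workflow: seeded
    synthetic data generation with known ground truth, ENVI cube input/output,
    single-band leaf segmentation and per-leaf mean-spectrum extraction,
    principal component exploration, a squeeze-and-excitation LSTM (SE-LSTM)
    concentration classifier with grid-search tuning and a plain-LSTM and
    PLS-DA baseline, characteristic-wavelength selection (SPA, GA, PSO, BOSS),
    Shapley-value band attribution, and two-dimensional correlation
    spectroscopy (2DCOS) with Noda sequencing of band responses.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    Matrix,
    tools
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    png,
    optparse
Config/testthat/edition: 3
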