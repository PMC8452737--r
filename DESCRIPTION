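Package: msivae
Title: Variational Autoencoder Manifold Learning and Peak Learning for
    Mass Spectrometry Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Unsupervised analysis of mass spectrometry imaging (MSI) data
    with a fully connected variational autoencoder. Learns a low-dimensional
    nonlinear manifold of pixel spectra, reconstructs the data generatively,
    identifies the m/z peaks that drive each latent feature through a
    weight-threshold rule on the network parameters, and segments tissue by
    Gaussian-mixture clustering of the latent features with automated model
    selection (BIC plus knee-point detection). Includes continuous-mode imzML
    and HDF5 input/output, total-ion-count normalization, local-maxima axis
    reduction, a synthetic phantom generator with known ground truth, and a
    train/apply/cross-validate workflow for 3D multi-section data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    jsonlite,
    mclust,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
SystemRequirements: HDF5 (libhdf5 headers and library)
NeedsCompilation: yes
Config/testthat/edition: 3
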