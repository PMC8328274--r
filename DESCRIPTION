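Package: plexuscount
Title: Automated Counting and Ganglionic Clustering of Enteric Neurons in
    Fluorescence Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An automated pipeline for structural analysis of the myenteric
    plexus from widefield fluorescence micrographs of HuC/D-immunolabeled
    tissue. Identifies neuronal somata as local intensity maxima after
    Gaussian smoothing and adaptive Otsu thresholding, clusters detected
    neurons into ganglia with DBSCAN (noise points reported as
    extraganglionic neurons), and produces watershed-style segmentations in
    which only the identified ganglia remain labeled. Computes plexus-level
    metrics: neuronal and ganglionic densities, ganglia-size distributions
    with a shifted negative-binomial model, and manual-versus-automated
    concordance regression. Includes a synthetic-micrograph generator with
    known ground truth for end-to-end validation, and a command-line
    interface for batch processing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
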