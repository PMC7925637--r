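Package: hepatoscope
Title: Quantitative Optical Microscopy of Liver Ultrastructure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Image-analysis toolkit for multiscale optical microscopy of
    liver tissue. Detects and sizes liver sinusoidal endothelial cell
    (LSEC) fenestrations in super-resolution membrane images via adaptive
    thresholding and marker-based watershed segmentation, with size
    filtering and diameter-distribution statistics. Unmixes hyperspectral
    coherent Raman (CARS/SRS) image cubes into per-pixel lipid and protein
    peak-amplitude maps by nonnegative least squares against a Gaussian
    peak basis. Reconstructs optical projection tomography (OPT) sinograms
    by filtered back-projection with a Shepp-Logan filter. Each analysis
    stage is paired with a seeded synthetic-data generator that produces
    inputs with ground truth, so parameter recovery is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    tiff,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, CellBiology, Visualization, Preprocessing
Collate:
    'hepatoscope-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'accessors.R'
    'synthetic.R'
    'fenestrae.R'
    'hyperspectral.R'
    'optrecon.R'
    'io.R'
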