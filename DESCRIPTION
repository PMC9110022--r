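Package: hsifuse
Title: RGB-Guided Unsupervised Super-Resolution of Hyperspectral Histology Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for whole-slide hyperspectral microscopy of stained tissue
    sections: radiometric calibration of transmittance cubes, feature-based
    affine registration of high-resolution RGB histology images to
    hyperspectral frames, sliding-window patch extraction with tissue
    filtering, and an unsupervised convolutional fusion network that
    reconstructs high-resolution hyperspectral patches from low-resolution
    hyperspectral input under RGB guidance.  Includes a reconstruction-quality
    metric suite (band-wise PSNR and MAE, spectral angle mapper, global SSIM),
    an Inception-style patch classifier with whole-slide probability-map
    stitching, and a Beer-Lambert phantom generator that produces paired
    high-resolution hyperspectral, RGB, and degraded low-resolution data for
    training and evaluation without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    pROC,
    rhdf5,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
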