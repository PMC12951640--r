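Package: mstta
Title: Multiple Sclerosis Lesion Segmentation with Test-Time Augmentation
    Ensembling and Test-Time Instance Normalization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Segmentation of multiple sclerosis white matter lesions from
    multicontrast brain MRI (T1w, T2w, PDw, FLAIR). A single 2.5D
    encoder-decoder network is applied under 24 multi-orientation test-time
    augmentations (3 cardinal planes x 8 dihedral operations); the binary
    predictions are aggregated into an integer confidence map and fused by a
    hysteresis-style two-threshold lesion detection and 26-connected growth
    procedure. Test-time instance normalization with batch-, instance- or
    condition-trained affine parameters provides robustness to domain shift
    and missing input contrasts. Includes a synthetic multicontrast phantom
    generator, lesion-wise evaluation metrics, a compact reference backbone
    with desk-scale presets, NIfTI input/output and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
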