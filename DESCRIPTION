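Package: pdacdetect
Title: Automatic Pancreatic Cancer Detection from CT Likelihood Maps with
    FROC Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Inference framework for fully automatic detection of pancreatic
    ductal adenocarcinoma (PDAC) on 3D contrast-enhanced CT. Implements
    automatic pancreas region-of-interest extraction from a coarse
    segmentation (downsample, upsample, spherical dilation, fixed margin),
    pancreas masking of voxel-level tumor likelihood maps, iterative
    peak-seeded candidate-lesion extraction, patient-level scoring and
    model ensembling, together with the complete evaluation protocol:
    patient-level ROC analysis, lesion-level FROC analysis with a DICE
    overlap hit criterion, partial AUC under the FROC curve, multi-model
    mean curves with confidence bands, and paired permutation tests for
    model comparison. Trained segmentation networks are replaced by a
    pluggable adapter contract; a synthetic abdominal phantom generator
    and a mock detector with controllable operating characteristics make
    the whole pipeline testable without trained weights or patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    parallel,
    RNifti,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
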