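Package: tempopet
Title: Temporal-Domain Radiomics for Dynamic PET
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for radiomic analysis of dynamic FDG PET. Computes
    standard three-dimensional intensity, shape and texture features (GLCM,
    GLRLM, GLSZM, NGTDM) on static and Patlak parametric images, plus causal
    temporal-domain co-occurrence and run-length features computed along the
    time axis of a 4D dynamic series. Includes population-based fixed-bin-width
    discretisation (Freedman-Diaconis), trilinear isotropic resampling with
    centre alignment, Patlak graphical analysis for voxelwise influx-constant
    and metabolic-rate images, Spearman redundancy and frame-duration
    robustness reports, and a synthetic 4D phantom with known voxel kinetics
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
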