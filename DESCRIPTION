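Package: macrovasc
Title: Macrovascular Correction and EEG-fMRI Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying inter-participant associations between
    resting-state fMRI metrics (fluctuation amplitude, seed-based functional
    connectivity, local and global functional connectivity density, BOLD
    sample entropy) and EEG source metrics (fractional band power, normalized
    total power, imaginary coherence, multiscale-entropy complexity index),
    together with a biophysically motivated macrovascular nuisance correction
    of the BOLD data based on lag-optimized regression of a venous reference
    signal. Includes a seeded synthetic cohort generator with ground-truth
    neuronal coupling and an injectable macrovascular confound, and a linear
    mixed-effects association stage with IQR outlier screening,
    Benjamini-Hochberg false discovery control, and paired goodness-of-fit
    comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    lme4,
    lmerTest,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
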