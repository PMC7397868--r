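Package: ricactivity
Title: WCE-Normalized RNA Interactome Capture Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Estimates in vivo poly(A)+ RNA-binding activities from RNA
    interactome capture (RIC) mass-spectrometry data by normalizing
    oligo(dT) pull-down intensities to whole-cell extract (WCE) protein
    abundances. Implements left-censored background imputation, median
    centering, an empirical-Bayes moderated t-test, comparative
    mutant-vs-wild-type shift coefficients with second-order Taylor
    uncertainty propagation and exact-moment pseudo-replicates,
    RNA-binding-domain classification from Pfam annotation, a
    synthetic-data generator with known ground truth, and
    four-parameter logistic fitting of fluorescence-anisotropy binding
    curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    limma,
    MASS,
    jsonlite,
    optparse
Config/testthat/edition: 3
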