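Package: sfindex
Title: Structure Function Index for Glaucoma Diagnosis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the Structure Function Index (SFI), a quantitative
    glaucoma-diagnosis index that fuses Humphrey 24-2 visual-field total
    deviation values and Heidelberg Retina Tomograph sector rim-area data.
    Per-point and per-sector continuous probabilities of abnormality are
    derived from empirical cumulative probability functions fitted to a
    reference cohort, and combined with the anatomical probability that a
    field location is linked to each optic-disc sector by retinal nerve
    fiber anatomy. Includes the SFI Hemifield Test (GHT-style cluster
    scores, paired superior-inferior differences and a diffuse-loss sum),
    ROC-based evaluation with Hanley-McNeil comparison of areas under the
    curve, and a synthetic paired-modality cohort generator so the whole
    pipeline can be exercised without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
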