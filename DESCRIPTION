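Package: episign
Title: Derivation and Classification of DNA Methylation Episignatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for deriving and applying DNA methylation episignatures
    from Infinium-style beta-value matrices: age- and sex-matched control
    selection, empirical-Bayes moderated differential methylation with
    false-discovery-rate control and correlation pruning to an independent
    probe set, classical multidimensional scaling with cluster-separation
    metrics, and a calibrated nu-SVM episignature classifier with a
    three-band (control / inconclusive / pathogenic) call rule. Includes a
    synthetic cohort generator with planted signatures and age, sex and
    batch nuisance structure so the full pipeline can be exercised and
    validated without access to restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    cluster,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
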