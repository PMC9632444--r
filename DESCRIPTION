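Package: qsmsci
Title: Quantitative Susceptibility and R2* Mapping of Silent Cerebral
    Infarcts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for quantitative MRI of
    silent cerebral infarcts (SCI) in white matter. Generates a digital
    brain phantom with ground-truth susceptibility and R2* maps,
    simulates multi-echo gradient-echo, FLAIR and T1-weighted
    acquisitions, reconstructs susceptibility maps by Tikhonov-regularized
    dipole inversion (with non-linear complex field fitting, Laplacian
    phase unwrapping and projection-onto-dipole-fields background
    removal) and R2* maps by log-linear relaxometry, segments SCI under
    FLAIR and FLAIR+T1w threshold definitions, pairs each lesion with a
    mirrored contralateral normal-appearing-white-matter region, and
    computes paired, Bland-Altman, ANOVA and correlation statistics on
    the lesion records.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
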