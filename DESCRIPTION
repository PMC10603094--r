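Package: scarmech
Title: Mechano-Structural and Proteomic Analysis of CNS Lesion Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis pipeline for multimodal studies of central
    nervous system scar tissue. Implements s0-moderated (SAM-style) differential
    abundance testing of label-free proteomics tables with permutation-based FDR
    control, matrisome annotation and a cross-species regulation screen;
    conversion of Brillouin frequency-shift maps and refractive-index data into
    absolute mass density, longitudinal modulus and compressibility with full
    Gaussian uncertainty propagation; cross-polarized OCT reflectivity and
    co-polarization-ratio quantification; Hertz and Kelvin-Voigt-Maxwell fitting
    of AFM force-indentation curves; and the accompanying effect-size statistics
    layer (Cohen's d, common-language effect size, boundary decision rule).
    Seeded generators for every input modality make the whole pipeline testable
    without access to the original imaging or mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
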