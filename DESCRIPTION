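Package: wfgica
Title: Group ICA and Brain-State Statistics for Wide-Field Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Decomposes multi-session wide-field calcium imaging recordings into
    group-level independent components with ICASSO stability analysis, R-index
    order selection and GICA back-reconstruction, and quantifies how graded
    anesthesia states modulate component activity. Includes image
    pre-processing (two-landmark registration, block downsampling, dF/F0
    normalization, zero-phase high-pass filtering, state concatenation),
    atlas-based component annotation with artifact flagging, threshold-based
    activation occurrence statistics with a bootstrap expected-occurrence null,
    binarized co-occurrence (phi) correlation analysis, repeated-measures ANOVA
    with Holm-corrected post hoc tests, and a synthetic mesoscale cortical
    dynamics generator with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    signal,
    MASS,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
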