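Package: thoravol
Title: Intra-Thoracic Fat Volumetry and Myocardial Scar Quantification
    from Signal-Threshold MR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Reference-tissue-normalized threshold segmentation of
    intra-thoracic adipose tissue on sagittal MR stacks, CT-anchored
    calibration of the signal-threshold multiplier against the
    conventional -190..-30 Hounsfield-unit fat window, signal-threshold
    versus reference myocardium (STRM) scar quantification on late
    gadolinium enhancement stacks, and the downstream cohort statistics
    (distribution-aware group comparisons, collinearity-screened linear
    regression, Bland-Altman agreement). Ships synthetic MR/CT thoracic
    phantoms, LV LGE phantoms and four-group cohort simulators with known
    ground truth so the whole pipeline is testable without patient data.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    oro.nifti,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
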