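Package: cfsa
Title: Clubbed Finger Severity Analysis from Finger-Profile Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies digital clubbing from lateral finger-profile images
    using the Lovibond (profile) angle at the nail base. Provides the full
    severity-analysis pipeline: a classical three-class segmenter
    (background/finger/nail) behind a pluggable segmenter contract, dorsal
    contour and anatomical landmark extraction, cosine-law triangle scoring
    with orientation-resolved profile angles, four-level severity grading,
    detection and segmentation loss functions, confusion-matrix metrics,
    and a synthetic finger-profile phantom generator with exact ground
    truth for end-to-end verification without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
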