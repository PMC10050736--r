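Package: kbsage
Title: Key Bone Search Decoding and RUS-CHN Bone Age Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Post-detector half of an automated bone-age-assessment pipeline
    built on the RUS-CHN (China-05) skeletal maturity method. Provides the
    163-class bone-by-grade label schema for the 13 key hand bones, the Key
    Bone Search (KBS) decoder that reduces raw detector candidates to one
    grade and box per bone after confidence suppression, a per-class
    non-maximum-suppression baseline with duplicate/missing accounting,
    maturity-score tables and standard-curve lookup for bone age (plus a
    gradient-boosted regression alternative), detection and regression
    evaluation (IoU, mAP at 0.5, confusion matrices, MAE/RMSE/RMSPE), CLAHE
    radiograph preprocessing, and a synthetic detector-output simulator so
    the whole chain is testable without radiographs or trained weights.
    Ships synthetic, non-clinical stand-ins for the unpublished China-05
    score tables; not for diagnostic use.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    xgboost,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
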