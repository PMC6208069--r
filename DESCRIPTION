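Package: kneepose
Title: Post-Operative 3D Component Position Analysis for Total Knee
    Arthroplasty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Registers pre-operative femoral and tibial bone surface models
    and implant fiducials into a post-operative CT frame and reports total
    knee arthroplasty component position: flexion/extension, varus/valgus and
    internal/external alignment angles, antero-posterior, medio-lateral and
    superior-inferior placement translations, and the six bony resection
    thicknesses, all referenced to patient-specific anatomic axes built from
    bony landmarks. Provides paired-point (Kabsch) and trimmed iterative
    closest point rigid registration, STL mesh input/output, landmark
    quality control, reproducibility summaries (maximum deviation from the
    mean with 95% confidence intervals), intra-class correlation
    coefficients with clinical interpretation bands, effective-dose
    conversion, and a parametric synthetic knee phantom generator with
    analytically known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    yaml,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pracma,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
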