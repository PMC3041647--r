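Package: vncn
Title: Virtual-Normal Reference Construction for SNP-Array Copy Number
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds an unbiased copy-number reference signal ("virtual
    normal") directly from a set of test (tumour) SNP-array intensity
    profiles, using any available normal set only as a template.  Common
    copy-number alterations are located in the log2 ratio of the test-set
    and template-set average intensities by mean-preserving segmentation
    or Gaussian-window filtering, and shifted back to baseline so that
    the reference keeps the probe-effect noise shared by the test batch
    but none of its common aberrations.  Includes aberration-tolerant
    GC-wave correction, per-sample raw copy-number estimation and
    segmentation, signal-to-noise QC metrics, SEG/BED writers, and a
    synthetic intensity simulator with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
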