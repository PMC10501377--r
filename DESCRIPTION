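Package: pfasnta
Title: Non-Target Screening of Per- and Polyfluoroalkyl Substances in
    Case-Control HRMS Feature Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering per- and polyfluoroalkyl substances
    (PFASs) in high-resolution mass-spectrometry feature tables from
    case-control study designs. Implements exact-mass formula arithmetic,
    CF2-normalized Kendrick mass defect computation, a feature
    prioritization cascade (replicate reproducibility, procedural-blank
    ratio, retention-time window, Kendrick-mass-defect window and
    case-control fold-change/t-test selection), CF2-homologue series
    detection, spectral-library fit scoring, suspect screening, diagnostic
    fragment and neutral-loss interpretation, and assignment of PFAS
    identification confidence levels (1a-5b). A synthetic-data generator
    plants PFAS homologous series on a realistic matrix background with
    ground truth for recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
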