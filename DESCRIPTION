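Package: icpd
Title: Information-Combining Peak Detection for High-Resolution LC/MS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Peptide feature detection for centroided high-resolution LC/MS maps.
    Candidate m/z traces are segmented into elution windows, expanded over charge
    state hypotheses, and scored by matching the observed isotope envelope --
    combined across all MS scans and charge states with matched-filter weights --
    against the theoretical averagine isotope pattern under a Gaussian noise model
    whose variance scales as a power law of peptide abundance. Includes a
    ground-truth LC/MS simulator (arbitrary elution shapes, charge-state
    dispersion, power-law noise, non-peptide contaminants) and ROC /
    precision-recall benchmarking utilities, plus a single-scan baseline scorer
    for quantifying the benefit of information combining.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mzR,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
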