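Package: rhizoN
Title: Nitrogen in Root Exudate Metabolomes from FT-ICR-MS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for nitrogen in root exudates under progressive
    drought, combining quantitative chemistry (total organic carbon and
    nitrogen balance, amino-acid nitrogen) with untargeted FT-ICR-MS
    metabolomics. Provides peak-list quality control (internal CH2-series
    calibration, signal-to-noise and mass-window filters, 13C isotopologue
    removal, blank subtraction, cross-sample alignment with prevalence
    filtering), exhaustive CHNOSP molecular formula assignment under
    accurate-mass tolerances, nitrogen-metabolome descriptors (relative
    abundance response ratios, elemental-class proportions, molecular-weight
    distributions, treatment-unique molecule selection), first-principles
    statistics (bootstrap two-sample tests with Benjamini-Hochberg
    adjustment, Kolmogorov-Smirnov tests, binary Bray-Curtis PERMANOVA,
    principal components with squared cosines), and a synthetic-data
    generator with known ground truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
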