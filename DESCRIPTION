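Package: glycanIndices
Title: Glycan Indices for IgG Fc N-Glycosylation Process Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative assessment of bioprocess-parameter
    effects on IgG Fc N-glycosylation. Parses Oxford-style glycoform
    shorthand (FA2G1S1, M5, ...) into structural records, computes
    site-occupancy glycan indices for fucosylation (FI), galactosylation
    (GI) and sialylation (SI) together with summative motif indices from
    relative-abundance glycoform distributions, pairs control and
    manipulated culture conditions, computes signed and absolute index
    differences with effect-magnitude classification, and aggregates
    results across studies. Includes an independent-site generator of
    synthetic biantennary glycoform distributions with closed-form index
    values for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
biocViews: Proteomics, Software, QualityControl
Config/testthat/edition: 3
RoxygenNote: 7.3.3
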