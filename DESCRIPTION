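Package: phthalscreen
Title: Diagnostic Fragment Ion Screening of Phthalate Metabolites in
    Non-Targeted LC-HRMS Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Non-targeted analysis (NTA) workflow for prioritizing and
    annotating phthalate monoester metabolites in negative-mode LC-HRMS
    acquisitions. Screens extracted ion chromatograms of the monophthalate
    diagnostic fragment ions (m/z 121.0295, 147.0088, 165.0193, supplementary
    134.0377) in both data-independent (in-source collision energy channels)
    and data-dependent (TopN ddMS2) acquisitions, enumerates CHO molecular
    formulas under elemental composition restrictions, applies intensity,
    two-of-three diagnostic-ion and procedural-blank rules, assigns
    Schymanski-style identification confidence levels against a standards
    library and suspect mass list with a pluggable retention-time predictor,
    and performs group differential analysis. A deterministic Q-Exactive-style
    acquisition simulator (DIA channels, TopN ddMS2 with dynamic exclusion,
    labelled standards, decoys, blanks) provides ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    mzR,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
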