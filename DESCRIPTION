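Package: dnastability
Title: Degradation Kinetics and Error-Correction Tradeoffs for DNA Data Storage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative design tools for DNA data-storage systems. Provides
    closed-form degradation kinetics for stored DNA (first-order backbone
    scission, freeze-thaw decay, Arrhenius temperature scaling, base-lesion
    accumulation), a strand-erasure and symbol-error channel model, analytic
    decoder-failure probabilities for concatenated inner-outer Reed-Solomon
    codes, an optimizer that maximizes information density (bits per
    nucleotide) subject to a residual decoder-error constraint, and a seeded
    Monte-Carlo channel simulator with a full GF(256) Reed-Solomon codec that
    serves as an independent oracle for the analytic results.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2,
    optparse
Config/testthat/edition: 3
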