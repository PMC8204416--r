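Package: linkwise
Title: Multi-Approach Record Linkage for Person-Level Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for linking person-level databases that lack a complete
    unique identifier, combining text standardisation and phonetic linkage
    keys, deterministic rule-based matching, multi-pass blocked probabilistic
    (Fellegi-Sunter) matching with EM-estimated agreement weights,
    post-processing reclassification and clerical-review decision support,
    and linkage-quality evaluation (false match, missed match and recall
    proportions with binomial confidence intervals). Includes a synthetic
    generator of paired person tables with Brazilian-style name structure,
    configurable corruption and per-field completeness profiles, carrying a
    known ground-truth link table so every stage can be tested without
    access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    stringi,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
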