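Package: swapdata
Title: Value-Swapping Anonymization for Relational Health Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A dictionary-driven anonymization pipeline for relational
    health data exported as delimited text tables. Each field is handled
    according to a reviewed privacy measure (no action, deletion, salted
    SHA-3 pseudonymization, or date randomization), after which row
    linkage is destroyed by independently permuting every column within
    ICD-10 entity groups (small groups merged up to a minimum size of 25)
    and thinning each table by exact-fraction random row deletion.
    Includes a synthetic tumor-registry generator so the whole pipeline
    is testable without patient data, and a verification module that
    audits a finished run for identifier leakage and structural fidelity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    openssl,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
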