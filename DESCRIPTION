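Package: paedradrisk
Title: Paediatric Radiography Effective Dose and Cancer Risk Communication
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Converts paediatric general radiography examinations into
    communication-ready radiation risk estimates. Maps a child's age and sex
    to a weight band through median weight-for-age reference data, resolves
    weight-banded tube settings (kVp, mAs) from an institutional exposure
    chart, attaches per-examination effective doses, converts dose to
    lifetime excess cancer-incidence risk by linear age interpolation of
    age- and sex-specific risk-coefficient tables, and renders the result as
    a 1-in-N statement, a Calman risk category, background equivalent
    radiation time (BERT) and an international flight-time equivalent.
    Includes a deterministic synthetic-data generator so the whole pipeline
    is testable without external reference tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
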