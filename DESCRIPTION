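Package: firearmtext
Title: Rule-Based Detection and Context Classification of Firearm Terms
    in Clinical Notes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for surveillance of firearm-violence exposure in
    electronic health record (EHR) data. Implements a three-category
    firearm term lexicon with character-offset matching over free-text
    clinical notes, structured-data cohort rules (ICD-10-CM external-cause
    codes and a behavioral-health SmartForm field), stratified note
    sampling with patient distinctness, a rule-based context categorizer
    with refinement filters for non-violence keyword hits (proper names,
    injectable "shot" mentions, "shooting" pain, EHR template phrases),
    small-cell-suppressed aggregate reporting, and a synthetic EHR corpus
    generator for end-to-end testing without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
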