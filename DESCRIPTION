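Package: gnkit
Title: Parsing, Cleaning, Fuzzy Matching and Cross-Mapping of Taxonomic
    Name-Strings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A names-management toolkit for biodiversity informatics.
    Parses scientific name-strings into their semantic components (genus,
    epithets, rank markers, authorship, annotations), produces complete and
    standard canonical forms, repairs idiosyncratic 'dirty' name-strings
    (concatenations, truncations, case damage) with rule-driven
    pre-processing, classifies name-strings into a revised usefulness scheme
    (species, genus, virus, common name, symbiont, negated, not useful),
    cross-maps checklists with restricted Damerau-Levenshtein fuzzy matching
    and nomenclatural heuristics, converts match features into calibrated
    sigmoid confidence scores, and mints deterministic content-derived UUID
    version 5 identifiers for name-strings. Includes a seedable generator of
    synthetic corrupted checklists with ground truth for offline evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stringi,
    tibble,
    yaml,
    readr,
    uuid,
    jsonlite,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
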