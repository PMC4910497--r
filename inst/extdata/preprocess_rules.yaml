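# Ordered repair rules for idiosyncratic name-strings. Each rule is a
# regular expression (PCRE) applied with gsub(); first tier to change the
# string logs its id and flags. The business rules can be adapted per
# source: copy this file, edit, and pass it to gn_rules().
rules:
  - id: strip-trailing-accession
    # trailing accession / voucher tokens joined by a separator:
    # "Didemnum_sp_AB211073.1", "Botryllus_planus_DQ346653",
    # "Hypothyris_anastasia_20507"
    pattern: "[_.]([A-Z]{1,4}[0-9][A-Za-z0-9.]*|[0-9][A-Za-z0-9.]*)$"
    replacement: ""
    flags: [tail_stripped]
  - id: strip-trailing-separator
    pattern: "[_0]+$"
    replacement: ""
    flags: [tail_stripped]
  - id: deconcat-underscore
    pattern: "_+"
    replacement: " "
    flags: [deconcatenated]
  - id: deconcat-zero
    # "Danio0reri": an interpolated zero between letters of a
    # capitalized-then-lowercase pair
    pattern: "(?<=[a-z])0(?=[a-z])"
    replacement: " "
    flags: [deconcatenated]
  - id: deconcat-x
    # "LissXtimor": X as separator only when flanked by a capitalized
    # token and a lower-case token, so hybrid formulas survive
    pattern: "^([A-Z][a-z]+)X([a-z]+)"
    replacement: "\\1 \\2"
    flags: [deconcatenated]
  - id: case-allcaps
    # "ARABIDOPSIS THALIANA" -> "Arabidopsis thaliana"; only applied to a
    # string of >=2 all-caps alphabetic tokens
    pattern: "^([A-Z])([A-Z]{3,}) ([A-Z]{3,})$"
    replacement: "\\1\\L\\2 \\L\\3"
    flags: [case_repaired]
  - id: case-capital-epithet
    # "Staphlococcus Aureus": species epithet with a capital
    pattern: "^([A-Z][a-z]+) ([A-Z])([a-z]+)$"
    replacement: "\\1 \\L\\2\\3"
    flags: [case_repaired]
  - id: case-lower-genus
    # "litoria ewingii": missing leading capital on the genus
    pattern: "^([a-z])([a-z]+ [a-z]{3,}( [a-z]{3,})?)$"
    replacement: "\\U\\1\\E\\2"
    flags: [case_repaired]
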