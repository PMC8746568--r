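Package: dissmet
Title: Identification of 3,6'-Disinapoyl Sucrose Metabolites from
    High-Resolution Mass Spectrometry Feature Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for in vivo drug-metabolite identification of
    3,6'-disinapoyl sucrose (DISS) from ultra-high-resolution ESI mass
    spectrometry data. Provides elemental-formula algebra with exact
    monoisotopic masses and electron-corrected adduct arithmetic for
    [M+H]+, [M-H]- and [M+Na]+ ions; molecular-formula enumeration under
    element, ring-double-bond and ppm constraints; depth-limited
    biotransformation-rule closure from a parent compound; cross-polarity
    feature grouping and candidate assignment; MS2 fragment sub-formula
    annotation with neutral-loss labelling; tissue-distribution
    differential analysis between treatment groups; behavioural summary
    statistics (recognition index, pooled t-test); and a seeded synthetic
    metabolome generator for end-to-end validation. Ships a plain-text
    fixture transcribing the published identification table for the DISS
    study in AD-model versus sham mice.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
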