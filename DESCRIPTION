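Package: sidexp
Title: Expected Plasma Strong Ion Difference and Whole-Blood Base Excess
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative acid-base physiology for CO2 tonometry of whole
    blood and isolated plasma. Models pH-induced redistribution of strong
    ions (chloride shift, albumin ionic binding) through the titrable
    imidazole charge of albumin and hemoglobin, predicts the expected
    plasma strong ion difference (SID) at any pH, estimates the
    noncarbonic whole-blood buffer value from titration curves, and
    computes whole-blood base excess by the Lang-Zander formulation.
    Includes Bland-Altman method agreement, a Fencl-Stewart comparator,
    a forward simulator of tonometry experiments, and fixtures encoding
    published group-mean tonometry tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
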