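Package: chromassay
Title: Chemometric Prediction of Fruit Biocompound Content from Pulp Color
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for spectrophotometric pigment quantification and
    chemometric calibration in fruit pulps. Converts raw absorbance
    readings into total anthocyanin (pH-differential method), total
    carotenoid (beta-carotene extinction at 450 nm) and total polyphenol
    (Folin-Ciocalteu) contents, fits linear color-to-content prediction
    models from CIE L*a*b* coordinates via least-squares normal equations
    with two-sigma residual filtering and partial-coefficient t tests,
    and validates methods against Horwitz coefficient-of-variation
    limits. Includes a synthetic-data generator reproducing the
    replicate structure of fruit-pulp calibration studies, packaged
    reference tables for six tropical and Andean fruits, and a
    pipeline with CSV/JSON reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
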