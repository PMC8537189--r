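Package: leafdepo
Title: Size- and Solubility-Resolved Quantification of Particulate Matter
    Retained on Plant Leaves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies atmospheric particulate matter (PM) retained on leaf
    surfaces from sequential elution/filtration gravimetry and total dissolved
    solids (TDS) readings, resolving PM by size class (>10, 2.5-10,
    0.1-2.5 micrometres, plus the soluble fraction) and by solubility pool
    (surface PM removable by water and brushing versus PM immobilised in
    cuticular wax and released by chloroform).  Computes leaf surface free
    energy and its polar and dispersive components from two-liquid contact
    angles by the Owens-Wendt method, and scales retention efficiency from
    unit leaf area to the individual tree and to unit green ground area via
    the leaf area index.  Includes species-comparison statistics (one-way
    ANOVA with Tukey HSD, correlation of retention with wettability and
    surface energy, k-means capacity clustering) and a forward simulator of
    complete field studies for end-to-end testing against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
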