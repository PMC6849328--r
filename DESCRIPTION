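Package: SRSquant
Title: Label-Free Quantification of Cellular Lipid Storage from Stimulated
    Raman Scattering Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated, selection-bias-free quantification of intracellular
    lipid storage from single-channel stimulated Raman scattering (SRS)
    images acquired at the 2845 cm-1 CH2 stretch. A sliding-window detector
    selects fields of view above a cellular-confluence gate, a two-layer
    thresholding scheme separates media from cells and then lipid droplets
    from the remaining intracellular signal, and a per-field ratio of lipid
    area to intracellular area (optionally normalized to cell number) is
    reported. Companion modules implement the surrounding assay arithmetic
    (radiolabel percent efflux with vehicle subtraction, percent viability,
    2^-ddCt relative expression), marker-masked ROI quantification with
    Pearson co-localization, Grubbs one-outlier-per-group screening, and
    the group-comparison statistics (t test, one-/two-way ANOVA with Tukey
    or Bonferroni post hoc tests). A seeded synthetic-data module generates
    SRS-like images and assay tables with exact ground truth so every stage
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
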