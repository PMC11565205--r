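Package: sorghumWUE
Title: Partitioning Intrinsic Water-Use Efficiency in Multi-Genotype
    Sorghum Trials
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for leaf-level water-use-efficiency screens
    of sorghum genotype panels under contrasting watering regimes.
    Partitions intrinsic water-use efficiency (iWUE = An/gs) into stomatal
    and non-stomatal (photosynthetic-capacity) components via a reference
    iWUE-gs curve, derives evaporative-flux hydraulics (Kleaf, Kplant and
    their resistances), computes phenotypic-change vectors (magnitude and
    angle theta) in An-Ci space between treatments, estimates broad-sense
    heritability and genotypic/phenotypic coefficients of variation from
    two-way ANOVA mean squares, and contrasts aquaporin haplotype groups
    with Tukey HSD letter displays. Includes a replicate-level trial
    simulator with known ground-truth variance components so every stage
    is testable without field data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
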