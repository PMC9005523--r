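Package: famMBD
Title: Familial Aggregation and Segregation Analysis of Malignant Blood
    Disorders in Pedigrees
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for genealogical analysis of familial malignant blood
    disorders (leukemias, lymphomas, myeloma). Reads and validates pedigree
    tables (CSV dialect or 6-column PED with a phenotype sidecar), enumerates
    proband-crude / affected-relative pairs within generation and
    healthy-intermediate caps, classifies paternal versus maternal lineage
    (including consanguinity loops), tabulates strictly vertical affected
    pairs, computes prevalence-based observed-versus-expected co- and
    contravariation statistics, runs the Haldane-Smith birth-order-effect
    rank-sum test with a Wilcoxon signed-rank control, and assesses
    anticipation (onset-age decline and prevalence shifts across
    generations). A synthetic pedigree generator implementing a
    sex-of-parent-dependent (imprinting-style) transmission model with
    configurable maternal drive, birth-order enhancement and anticipation
    provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
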