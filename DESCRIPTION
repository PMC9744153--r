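Package: vagcst
Title: Extended Community State Type Classification for the Vaginal Microbiome
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Rule-based assignment of extended vaginal community state types
    (CST I-V with IV-A/IV-B/IV-C subtypes and CST VI-IX) from taxa
    relative-abundance tables, together with the supporting microbiome
    statistics: a canonical taxon registry with synonym resolution and
    functional groups (Lactobacillus, Gardnerella, Prevotella, taxa with
    high pathogenic potential), abundance-table input/output with
    rarefaction and group summaries, Shannon and Bray-Curtis diversity with
    PERMANOVA and pairwise Kruskal-Wallis group tests, a normality-gated
    Pearson/Spearman correlation workflow with confidence intervals,
    complete-linkage de-novo clustering, and a Dirichlet-multinomial
    synthetic cohort generator with constraint-based fixture construction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    vegan,
    ape,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
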