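Package: atlasenrich
Title: Regional Expression Enrichment of Gene Sets in Brain
    Transcriptomic Atlases
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Builds gene-by-region reference matrices from multi-donor
    brain expression atlases (probe-to-gene collapsing, within-region
    ranking, cross-region z-scoring, donor averaging), scores gene sets
    for region-specific expression with a threshold-free AUROC statistic
    backed by Mann-Whitney significance and Benjamini-Hochberg false
    discovery rate control, tests gene-list overlaps against cell-type
    marker sets with hypergeometric statistics, and performs
    batch-stratified two-condition single-cell differential expression
    with Fisher's-method meta p-values for up- and down-regulation.
    Includes seed-deterministic synthetic-data generators with planted
    ground truth for end-to-end validation, and a pipeline driver that
    orchestrates reference building, enrichment, overlap and
    differential-expression stages from a single configuration file.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
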