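Package: erktox
Title: Scoring ERK-Hyperactivation Toxicity Screens and Negative-Feedback Regulator Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multi-stage analysis pipeline for studies of ERK-pathway
    hyperactivation toxicity in RTK-RAS-mutant lung adenocarcinoma cells.
    Implements pooled CRISPR knockout screen scoring (read-depth
    normalization, pseudocount log2 fold-changes against a plasmid reference,
    and gene ranking by the second-most enriched or depleted sgRNA), a
    Bonferroni-corrected differential-expression scan of negative feedback
    regulators (DUSP, SPRY and SPRED families) with reverse-phase protein
    array association analyses, and viability analysis (relative viability,
    four-parameter logistic dose-response fits, IC50-based sensitivity
    classification, drug-rescue normalization, delta-delta-Ct and
    densitometry ratios). Includes seeded synthetic-data generators with
    planted ground truth for every input the pipeline consumes, and a small
    command-line interface over the same functions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
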