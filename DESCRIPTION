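Package: xireact
Title: Allele-Specific Analysis of X-Chromosome Inactivation Escape and
    Reactivation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies X-linked heterozygous variant sites and genes as
    reactivated, full-escape, late-silenced, or inactive from replicate
    allelic read counts collected along a neural differentiation axis
    (iPSC, NPC, neuron). Pools allelic counts per cell type, estimates the
    probability of expression from the inactive X-chromosome, and applies
    one-sided binomial tests with Benjamini-Hochberg correction. Collapses
    variant calls to gene-level categories with inverse-variance
    meta-analysis of logit-transformed proportions. Provides resampling
    gene-set statistics (overlap enrichment, transcription-start-site
    clustering, chromatin-state comparison, sex-bias contingency tests),
    per-cell biallelic-expression scores from allele-resolved UMI counts
    with pseudotime binning, and a per-cell transcriptional-deviation
    statistic. A seeded synthetic-data generator produces every input with
    known ground truth so the full pipeline is testable without external
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
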