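Package: dualomics
Title: Paired Transcriptome-Proteome Differential Expression, Nine-Quadrant
    Concordance and Differential-Response Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream integration of paired bulk RNA-seq count matrices and
    data-independent-acquisition (DIA) proteomics intensity matrices from
    multi-genotype stress experiments. Provides FPKM/CPM quantification,
    replicate quality control, simple deterministic differential-expression
    engines for both omics layers (Welch or Student t on log2 values with
    Benjamini-Hochberg adjustment), Venn accounting of DEG/DEP sets,
    nine-quadrant transcript/protein concordance classification, a
    cross-genotype differential-response fold-change screen, hypergeometric
    term enrichment with directional z-scores, and a negative-binomial /
    log-normal synthetic-data generator with a complete ground-truth answer
    key. Ships a published 36-gene fold-change table from a salt-stress
    experiment on wild-type and ZmPDI-overexpressing Zoysia matrella as a
    worked example for the screen.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
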