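Package: xenofate
Title: Cell-Fate Analytics for Xenografted Brain-Organoid Single-Cell Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for human brain organoids transplanted into
    mouse brain, starting from dual-genome aligned count matrices. Provides
    species demultiplexing of mixed human/mouse droplets by human-transcript
    ratio, pseudo-bulk expression profiles with PCA, transcriptome-distance
    clustering and rank-correlation mapping to reference panels, an in-house
    Wilcoxon differential-expression engine with Benjamini-Hochberg
    correction and the standard filter thresholds, fold-change quadrant
    concordance and signed host-alignment scores, hypergeometric gene-set
    over-representation, astrocyte morphometry on SWC skeletons (Sholl
    profiles, branch statistics, neurite colocalization), and calcium-trace
    response analysis. A synthetic-data module generates every input with
    known ground truth so the full pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
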