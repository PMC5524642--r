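Package: plateseq
Title: Pooled Well-Barcoded 3' RNA-Seq Screen Processing and Simulation
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing toolkit for pooled, well-barcoded 3'-end RNA-Seq
    screens (PLATE-Seq-style plates): design and decoding of single-error-
    correcting well barcodes, demultiplexing and strand-specific unique-
    mapping gene counting from transcriptome alignments, per-well QC and
    gene-detection saturation curves, variance-stabilized vehicle-referenced
    perturbation signatures with classical MDS, simplified regulon-based
    protein-activity inference (two-tail weighted rank enrichment with an
    analytic normal null), and replicate coefficient-of-variation noise
    analysis. Includes a full synthetic-run simulator (toy transcriptome,
    negative-binomial plate counts with planted effects, barcoded paired
    FASTQ) with ground truth, so every stage can be exercised and validated
    without external sequencing data, plus a YAML-configured end-to-end
    pipeline and command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    data.table,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    vegan,
    optparse
Config/testthat/edition: 3
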