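Package: sagqc
Title: Quality Assessment and Reference-Based Evaluation of Single-Cell
    Amplified Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Metrics and simulation tools for evaluating single-cell
    amplified genomes (SAGs) against a sequenced reference: read-mapping
    and coverage-breadth summaries, downsampling saturation analysis,
    contamination screening (taxonomy tables, tetranucleotide-frequency
    clustering, GC bimodality, 16S rDNA OTU profiling), scaffold-to-
    reference recovery with gene-completeness thresholds, BLAST-style
    average nucleotide identity with overlap merging, annotation scoring
    (Jaccard overlap, unique-gene recovery, protein-domain set algebra),
    and translated phylogenomic-marker recovery with supermatrix
    occupancy accounting. Includes a synthetic MDA-bias read simulator
    with ground truth so every stage can be exercised at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    cluster,
    mclust,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
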