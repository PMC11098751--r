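Package: scmut
Title: De Novo Somatic SNV Detection in Barcoded Single-Cell Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects somatic single-nucleotide variants directly in barcoded
    single-cell sequencing data (droplet scRNA-seq, sciATAC-seq) without a
    matched DNA reference. Reads are partitioned by annotated cell type,
    per-site nucleotide counts are collected per cell type and per cell
    barcode, and candidate variants are separated from sequencing noise with
    a beta-binomial background-error test fitted on non-neoplastic training
    counts. A cell-type-exclusivity test removes germline polymorphisms, and
    a hard-filter cascade (panel of normals, homopolymer proximity,
    clustered-variant and minimum-support rules) removes recurrent artefacts.
    Downstream analytics include callable-site and mutational-burden
    estimation at cell-type and single-cell resolution, trinucleotide
    (96-class) mutational spectra with genome-background renormalization,
    single-cell genotyping with mutant-cell fractions and clonal clustering,
    and benchmarking of single-cell call sets against DNA truth sets with
    bootstrap confidence intervals. A synthetic-data generator reproduces the
    statistical structure the caller assumes, so the full pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings,
    IRanges,
    GenomicRanges,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
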