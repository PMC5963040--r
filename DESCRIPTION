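Package: TEforge
Title: De Novo Transposable-Element Detection, Classification and
    Nested-Library Genome Annotation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A self-contained toolkit for de novo annotation of
    transposable elements (TEs) in genome assemblies. Combines four
    detection approaches (similarity to a nucleotide databank and to
    protein domain consensi, structural mining of LTR/TIR/TSD/poly-A
    signatures, repetitiveness-based consensus building, and k-mer
    assembly from unassembled reads), reduces redundancy by exact
    containment, classifies candidates under the Wicker hierarchy with
    explicit autonomy rules, groups them into 80-80-80 families, and
    annotates the genome with three nested ("Russian doll") libraries,
    reporting genome proportions per category. Includes a coverage-score
    benchmarking framework against a reference family library, an
    expression/peptide activity-crossing stage, and a synthetic-genome
    generator that plants structurally faithful TE copies with truth
    tables so every stage is testable without external databanks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3),
    Biostrings,
    GenomicRanges
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    rtracklayer,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
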