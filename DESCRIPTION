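Package: stemloopscreen
Title: Genome-Wide Detection of Stop-Codon-Proximal mRNA Stem-Loops and
    Readthrough Reporter Quantification
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for screening annotated genomes for mRNA stem-loop
    (hairpin) structures located immediately 3' of stop codons, a sequence
    context implicated in programmed stop codon readthrough (SCR). The
    package extracts fixed-width 3'UTR windows downstream of each gene's
    first stop codon from a genome FASTA plus GFF3 annotation, predicts or
    ingests RNA secondary structures (RNAfold-style dot-bracket files, or a
    built-in maximum-base-pairing folder), classifies hairpin elements
    against configurable span/loop/bulge criteria, designs destabilizing,
    stabilizing and structure-compensatory stem-loop sequence variants, and
    quantifies dual-reporter readthrough efficiencies. A deterministic
    synthetic-fixture generator produces toy genomes with planted hairpins
    of known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    GenomeInfoDb,
    S4Vectors,
    IRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Sequencing, Annotation, SecondaryStructurePrediction,
    GenomeAnnotation, Transcriptomics
RoxygenNote: 7.3.3
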