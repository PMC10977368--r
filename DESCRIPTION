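Package: aondesign
Title: Splice-Switching Antisense Oligonucleotide Design and In Silico
    Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing splice-switching antisense oligonucleotides
    (AONs) that knock down a gene by forcing skipping of an out-of-frame
    internal exon. The package parses gene annotations (GFF3/GTF) and genome
    sequences, classifies exon reading-frame status, simulates exon skipping
    with premature-termination-codon and nonsense-mediated-decay calls,
    derives per-base accessibility (ss-count) profiles from an ensemble of
    predicted secondary structures, scans exons for splicing enhancer and
    silencer motifs, evaluates candidate oligos by nearest-neighbor
    hybridization thermodynamics (GC%, Tm, binding free energy, self- and
    cross-dimerization), and ranks candidates with an explicit composite
    score. An in-silico nested RT-PCR engine predicts amplicon sizes on
    wild-type and skipped templates, and a counts-per-million filter
    reproduces the standard expression pre-filtering step. A synthetic-data
    module generates fully specified toy gene models and count matrices so
    the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    jsonlite,
    methods,
    Rcpp,
    rtracklayer,
    S4Vectors,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    edgeR,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
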