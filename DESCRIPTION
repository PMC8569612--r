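Package: plantElements
Title: Design and Molecular Characterization of Synthetic Plant Expression
    Elements
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for deriving, screening and molecularly characterizing
    synthetic plant expression elements: promoters with 5' UTR leaders,
    introns, and 3' UTR terminators. The package extracts anchored training
    windows (TSS, splice sites, polyadenylation sites) from a genome and its
    annotation, computes position-specific word enrichment between foreground
    and background training sets, generates candidate elements from positional
    nucleotide profiles under hard sequence constraints (TATA-to-TSS spacing,
    ATG-free leaders, canonical splice sites, near-upstream elements and
    T-rich tracts), screens designs for shared-identity runs against source
    genomes and for unintended open reading frames, and builds transversion
    knockout variants of annotated motifs. Transcript-level readouts are
    quantified from spliced alignments: splice-junction usage accounting,
    adapter-anchored transcription start site and polyadenylation site
    distributions, and qPCR read-through by the 2^-ddCt method. A read
    simulator with known truth makes the whole characterization path testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    GenomeInfoDb,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    data.table,
    yaml,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: Software, SequenceMatching, MotifDiscovery, GenomeAnnotation,
    Transcriptomics, AlternativeSplicing
RoxygenNote: 7.3.3
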