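Package: arichclip
Title: iCLIP Binding-Site Definition and A-Rich Sequence Context Analysis
Version: 0.1.0
Authors@R: person("arichclip", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Tools to characterize where an RNA-binding protein crosslinks
    relative to A-rich sequence elements from iCLIP data. Implements
    barcode-quality filtering and crosslink-event extraction, a local
    negative-binomial peak caller with iterative refinement into uniform 9-nt
    binding sites, the abundance-corrected signal-over-background (SOB)
    binding-strength statistic, A-rich stretch detection by windowed
    maximization, empirical 4-mer enrichment z-scores against resampled 3'
    UTR backgrounds, poly(A)-tail diagnostics on unmapped reads, and
    metaprofiles around polyadenylation sites. A synthetic-data generator
    with known ground truth makes every stage testable without external
    accessions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml,
    digest,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
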