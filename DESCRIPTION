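Package: meiometh
Title: Simulation and Analysis of Replication-Coupled DNA Demethylation in
    Meiotic Prophase
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study transient, replication-coupled reduction of DNA
    methylation at the onset of meiosis. Implements a duplex-resolved
    simulator of CpG dyad methylation through replication-timing-ordered
    semiconservative replication with tunable maintenance methylation;
    simulation and duplex-aware calling of hairpin-bisulfite amplicon reads
    against the mouse LINE-1 (L1MdTf) promoter consensus, including
    per-dyad methylated/hemimethylated/unmethylated classification;
    WGBS-style per-CpG summarization (M-bias clipping, strand merging,
    common-CpG restriction, CpG bins, fixed-width windows, feature
    aggregation, coverage windows); smoothing-based detection of large
    differentially methylated blocks with intersection accounting; and
    correlation of stage methylation with replication timing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
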