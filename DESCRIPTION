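Package: circkit
Title: Back-Splice Junction Detection, Annotation and Quantification of Circular RNAs
Version: 0.1.0
Authors@R: person("circkit", "maintainers", email = "circkit@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for cataloging circular RNAs (circRNAs)
    from RNA-seq reads. Provides a synthetic-data generator (toy genomes with
    canonical GT/AG gene models, planted circRNAs, ring-sampled reads, RNase R
    digestion, qPCR Ct tables), an anchor-based back-splice junction caller
    with GT/AG breakpoint refinement, host-gene annotation into the standard
    five categories, circular-to-linear ratio (CLR) and TPM quantification,
    tiered tissue-expression classification with hierarchical clustering,
    junction-spanning ORF and tryptic-peptide prediction, and spike-in
    normalized delta-delta-Ct analysis of validation qPCR experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
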