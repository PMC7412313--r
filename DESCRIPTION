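Package: graftmobile
Title: Detection of Graft-Transmissible Mobile mRNAs from Heterograft RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies scion-derived (graft-transmissible) mRNAs in rootstock
    RNA-seq samples from interspecies heterografts. Read pairs are passed
    through a sequential classification cascade: alignment to the rootstock
    transcriptome with a permissive edit-distance cap, subtraction of reads
    perfectly matching non-grafted control libraries, and alignment to the
    scion transcriptome with a strict cap; transcripts supported in a minimum
    number of biological replicates are called mobile per growth condition.
    Includes a k-mer-seeded banded edit-distance aligner, adapter/quality/rRNA
    read filtering, RPKM quantification, reciprocal-best-hit orthology mapping
    with an internal Smith-Waterman scorer, hypergeometric set-enrichment
    statistics with covered-percentage reporting, Venn partitioning of
    condition-specific mobile sets, and a synthetic heterograft experiment
    generator with full ground-truth bookkeeping.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
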