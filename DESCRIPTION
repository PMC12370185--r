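Package: pioneerseq
Title: Design and Analysis of TFBS-Tiled Nucleosome Library Binding Assays
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for high-throughput nucleosome binding assays in which a
    transcription factor binding site (TFBS) is tiled at base-pair resolution
    across nucleosome positioning sequences and assembled into an
    oligonucleotide library. Covers library design (motif scanning and
    scrubbing, per-position tiling, primer flanking, selection of in
    vivo-targeted nucleosome windows), processing of paired-end gel-band and
    MNase-digest reads against the designed library (quality trimming, pair
    merging, primer removal, identity-threshold mapping), quantification of
    TF-nucleosome binding with a relative-supershift log2 statistic against
    nonspecific control sequences, MNase protection and fragment-center
    analytics, and a fully seeded simulator that generates demo libraries,
    band read pools, and fragment pools with ground truth so every stage can
    be tested end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    dplyr,
    ggplot2,
    jsonlite,
    methods,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
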