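Package: mirfree
Title: Reference-Free Plant miRNA Discovery from Small RNA, Transcriptome
    and Degradome Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery and validation of plant microRNAs in species without a
    sequenced genome. Small RNA reads are adapter-trimmed, collapsed and grouped
    into clusters of perfectly co-aligned sequences; clusters with a dominant
    20-21 nt size signal are ranked as novel miRNA candidates. Conserved families
    are assigned by ungapped overlap alignment against a mature-miRNA catalogue
    with a mismatch budget, precursor hairpins are validated on assembled
    transcripts with a deterministic base-pair-maximization fold, miRNA:target
    duplexes are scored with the plant mismatch/G:U wobble rule, and predicted
    cleavage sites are confirmed against degradome (PARE) tags via T-plots with
    tags-per-million normalization. A seeded simulator generates synthetic
    transcriptomes, hairpins, multi-library small RNA reads and degradome tags
    with full ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
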