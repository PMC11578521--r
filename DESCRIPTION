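Package: uorfexonizer
Title: Re-Interpreting Upstream ORFs as Novel First Coding Exons of Existing Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully testable pipeline for evaluating whether
    catalogued upstream open reading frames (uORFs) in 5' untranslated regions
    could act as novel first protein-coding exons of their downstream genes
    rather than as independent genes on bicistronic transcripts. Implements
    weighted cross-genome conservation scoring of uORF sequences (sequence
    match, 5'UTR containment, gene-locus match; 0-7 scale with a distance
    exception and a curation bump), construction of uORF-connected transcripts
    from experimental splice junctions or scanned GT donors paired with
    annotated MANE acceptors under a splice-score threshold, open reading
    frame validation (premature stop, frame, minimum CDS length fraction),
    and comparison of per-residue structure-confidence (pLDDT) means between
    novel and reference proteins. Ships a deterministic synthetic-data
    generator producing toy genomes, annotations, uORF catalogues, junction
    evidence and mock splice/pLDDT scorers with ground-truth labels for every
    pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    rtracklayer,
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
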