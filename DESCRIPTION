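Package: tagscan
Title: Gene Identification in Genomes by Protein Tag Searching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
                  role = c("aut", "cre"))
Description: Searches nucleotide sequences for short, family-diagnostic
    protein motifs ("tags"). A partially specified amino-acid tag such as
    P-XXX-D-X-K-X-G (the inositol-binding consensus of the inositol
    polyphosphate kinase superfamily) is compiled by reverse translation
    into a degenerate nucleotide pattern of constrained codon boxes
    separated by gaps. Genomic sequence is scanned on both strands with
    configurable mismatch, skip and box-swap budgets and optional
    C-to-U RNA-editing-aware matching for plant organellar DNA. Matches
    are expanded into candidate gene regions: a flanking window is
    extracted, translated in the tag-anchored frame, screened by a
    wildcard residue-composition rule and a stop-free open-reading-frame
    span, and ranked against reference kinase proteins by Smith-Waterman
    local alignment. A synthetic-genome simulator with planted,
    codon-randomized tag instances and simulated editing supports
    validation and false-positive calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
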