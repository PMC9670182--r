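Package: hybsignal
Title: Detecting Allopolyploid Hybridization from Multi-Labeled Gene Family Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect allopolyploidy and hybridization events from
    collections of multi-copy nuclear gene family trees. Gene family trees are
    filtered by taxon coverage, outgroup presence, group representation and
    family monophyly; pruned to one best copy per non-hybrid species while
    retaining all copies of putative hybrids; and converted to multi-labeled
    (MUL) single-copy trees in which each hybrid appears as up to two tips
    labeled by parental lineage. Hybridization signal is then summarized by
    counting per-clade gene-tree concordance and conflict against a reference
    phylogeny and by quartet-score maximization over the labeled trees. A
    multispecies-coalescent simulator with an allopolyploidy event, paralog
    injection and sequence-length assignment generates synthetic datasets with
    machine-readable truth records so the whole pipeline can be validated.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape (>= 5.0),
    phangorn,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
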