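Package: splicetriage
Title: Splice-Acceptor Variant Consequence Analysis and Lynch Syndrome Triage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working out the consequences of 3' splice-acceptor
    variants in coding genes, modelled on the analysis of MSH2 c.793-1G>A in a
    Lynch-syndrome family: position-weight-matrix acceptor scoring with
    percent-change (delta consensus value) arithmetic and loss/gain calls,
    cryptic-acceptor scanning, reconstruction of aberrant transcripts (exon
    truncation, intron retention, exon skip), translation to the premature
    termination codon with HGVS frameshift nomenclature and a
    nonsense-mediated-decay call, minigene/RT-PCR band-size prediction, and
    the rule-based clinical classifiers used to triage families (NCI
    five-marker microsatellite-instability panel, mismatch-repair
    immunohistochemistry patterns, Amsterdam II pedigree criteria). Includes a
    deterministic synthetic-data generator producing toy genes with planted
    cryptic acceptors and engineered stop codons so every stage is testable
    without reference downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stringr,
    tibble
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
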