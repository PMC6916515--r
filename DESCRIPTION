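Package: allomark
Title: Missing-Self Allorecognition Analysis for Ascidian Hemocyte Contact Reactions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for allorecognition in the solitary ascidian
    Halocynthia roretzi. Converts replicated phenol-oxidase (OD520) readings
    from mixed-hemocyte incubations into a binary contact-reaction (CR)
    matrix, clusters individuals by Manhattan distance with from-scratch
    UPGMA (group-average) agglomeration, groups individuals into discrete
    antibody-induced activity classes, calls presence/absence spot profiles
    over the twelve HrSMLP1 2D-DIGE glycoform spots, evaluates the
    missing-self recognition rule (reactive iff profiles differ) against
    observed CR, searches exhaustively for minimal discriminating spot sets,
    and simulates calibrated synthetic populations so every stage is
    testable end to end. A small sequence-feature module computes ORF
    translation, average molecular mass, isoelectric point and
    N-glycosylation sequons for the self-marker cDNA.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    seqinr
Suggests:
    testthat (>= 3.0.0),
    ape,
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
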