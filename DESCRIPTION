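Package: paleomilk
Title: Detection of Milk Beta-Lactoglobulin Peptides in Ancient Dental
    Calculus Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for identifying the ruminant whey protein
    beta-lactoglobulin (BLG) in tandem mass-spectrometry peak lists from
    archaeological dental calculus. Builds a multi-species BLG reference
    peptidome (semi-tryptic in-silico digestion, diagenetic modifications,
    reversed-sequence decoys), matches MGF spectra under instrument
    tolerances with a binomial ion score, controls error by target-decoy
    false discovery rate, assigns dairy species by lowest-common-ancestor
    consensus of taxon-diagnostic peptides, computes protein coverage and
    regional cohort summaries, and maps lactase-persistence phenotype
    frequencies with sample-size-weighted Gaussian kernel smoothing. A
    ground-truthed synthetic-data generator makes every stage testable
    without raw-data downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
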