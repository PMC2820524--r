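Package: tecoopt
Title: Transposable-Element Annotation, Binding-Site Scanning, and Insertion
    Dating for Regulatory Co-Option Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing how a DNA transposon can donate a
    transcription-factor binding site to a gene promoter: de-novo
    characterization of candidate class II elements (terminal inverted
    repeats, target-site duplications, ORF content, majority-rule IUPAC
    consensus), BLASTN-like seed-and-extend copy counting under
    identity/coverage filters, position-weight-matrix scanning with exact
    dynamic-programming p-values and expected-hit enrichment, pairwise
    promoter comparison with large-indel region segmentation and
    insertion-versus-loss classification, and Kimura-2-parameter divergence
    dating of an element insertion on a calibrated, clock-linearized
    neighbor-joining tree. Seeded synthetic-data generators provide every
    input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
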