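Package: idiokit
Title: Anti-Idiotypic Antibody Discovery Campaign Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational toolkit for anti-idiotypic (anti-ID) antibody
    discovery campaigns against therapeutic antibodies. Covers design of
    CDR-grafted framework-control Fabs (template-based Kabat-style numbering,
    germline consensus frameworks, closest-framework selection, CDR grafting),
    clone CDR-diversity analysis (zero-gap-penalty pairwise differences,
    uniqueness deduplication, neighbor-joining trees), ELISA hit calling with
    OD thresholds, global 1:1 Langmuir kinetics fitting of SPR sensorgrams,
    epitope-type classification (antigen blocking / non-blocking /
    antigen-drug-complex specific), epitope binning from pairwise competition
    matrices, and signal-to-noise driven selection of pharmacokinetic sandwich
    pairs and anti-drug-antibody bridging positive controls. A synthetic-data
    generator emulates every wet-lab input with recorded ground truth so the
    whole pipeline is testable without instrument exports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
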