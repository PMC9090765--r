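Package: neoparp
Title: Pre-Treatment Multi-Omic Biomarkers of PARP-Inhibitor Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for pre-treatment biomarker analysis of germline
    BRCA-mutant breast tumors treated with neoadjuvant PARP inhibition.
    Computes homologous-recombination-deficiency scar scores from
    allele-specific copy-number segments (weighted genome instability
    index, large-scale state transitions, telomeric allelic imbalance),
    applies consensus somatic-variant filtering and tumor mutation
    burden, refits 96-channel mutational-signature exposures by
    constrained forward selection, runs preranked gene-set enrichment
    with a permutation null and leading-edge extraction, and combines
    shieldin (SHLD2) loss with hypoxia and EMT/stem-cell expression
    signatures into a composite resistance classifier. Seeded synthetic
    generators emulate every input so the whole pipeline is testable
    without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
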