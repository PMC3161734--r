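Package: circaflux
Title: Elementary Flux Mode Analysis of Circadian Metabolic Regulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to study how circadian translational control reshapes the
    metabolic capabilities of a stoichiometric network. The package parses and
    validates metabolic models with per-metabolite carbon counts, enumerates
    elementary flux modes (EFMs) with an exact integer double description
    algorithm, scans 3'-UTR sequences for perfect (UG)k dinucleotide repeats
    (the binding motif of the Chlamydomonas reinhardtii clock factor CHLAMY1),
    maps motif hits to regulated reactions, and quantifies how complete
    (knockout) or partial (weighted) downregulation of the regulated enzymes
    shifts the carbon-yield distribution over all EFMs. Synthetic generators
    for networks, UTR sets with planted motifs, and proteomes provide ground
    truth for testing, and a reduced nitrogen-metabolism core model of
    C. reinhardtii is included as a worked fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    xml2,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
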