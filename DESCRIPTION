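Package: abhumanize
Title: Structure-Guided Antibody Humanization by CDR Grafting and Contact Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for humanizing murine antibody variable
    domains. Assigns Kabat numbers and region labels to VH/VL sequences,
    ranks human germline framework acceptors with upper-hydrophobic-core
    preservation checks, grafts donor CDRs onto the selected acceptor,
    analyses framework-to-CDR residue contacts in Fv structure models to
    recommend back mutations, and predicts binding free energy and
    dissociation constants of antibody-antigen complexes from classified
    interfacial contacts and non-interacting surface composition. Includes
    generators for synthetic Fv sequences, toy Fv structures with planted
    contacts, and two-chain complexes with known interface composition, so
    every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
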