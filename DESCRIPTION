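Package: sortseqthermo
Title: Sort-Seq Energy Matrices and Thermodynamic Models of Simple Repression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping transcription-factor binding-site sequence to
    binding energy with massively parallel reporter (Sort-Seq) data. Simulates
    mutagenized operator libraries sorted into fluorescence bins, infers linear
    sequence-to-energy matrices by mutual-information-maximizing
    Metropolis-Hastings sampling, converts matrices to absolute kBT units via
    scaling-factor inference or least-squares anchoring, and couples them to
    statistical-mechanical models of simple repression and allosteric
    induction to predict fold-change, binding energies, and designed induction
    phenotypes (leakiness, saturation, dynamic range, EC50).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    seqinr,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
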