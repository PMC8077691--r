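Package: chemnmt
Title: Neural Machine Translation Between Molecular String Notations and
    Systematic Chemical Names
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for sequence-to-sequence translation
    between molecular line notations (SMILES/SELFIES) and systematic
    IUPAC-style names. Provides corpus construction (molecule filtering,
    SELFIES interconversion, paired dataset assembly and token-balanced
    splitting), tokenizers for SELFIES strings and chemical names, a GRU
    encoder-decoder translator with additive attention trained by teacher
    forcing with padding-masked cross-entropy, and an evaluation protocol
    based on sentence BLEU, name round-trip validity and
    substructure-fingerprint Tanimoto similarity. A built-in rule-based
    nomenclature generator for a restricted acyclic molecule family
    supplies exact ground-truth training pairs and a name-to-structure
    backend without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineOB,
    ChemmineR,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
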