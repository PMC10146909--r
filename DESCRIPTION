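Package: klhlscan
Title: Conservation Profiling and Cysteine-Code Analysis for Kelch-Like Protein Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for comparative analysis of the
    Kelch-like (KLHL) protein family and its reference member Keap1.
    Selects family members by BTB/BACK/Kelch domain architecture, builds
    neighbor-joining trees from maximum-likelihood JTT distances over
    conserved alignment blocks with bootstrap support, profiles per-column
    conservation (rank classes, consensus, frequency-weighted penalty
    scores, clade-informative bimodal positions), reports the "cysteine
    code" of a reference protein (per-cysteine conservation at ortholog,
    clade and family level, flanking basic residues, motif scans), and
    measures cysteine-to-basic-residue distances in 3D structures. A
    synthetic family generator with planted conservation and cysteine
    patterns provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    bio3d,
    Matrix,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
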