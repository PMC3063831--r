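Package: setstruct
Title: Gene Structure, Intron Phase and Phylogeny of Plant SET Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A comparative-genomics toolkit for histone methyltransferase
    (Su(var)3-9 class SET) gene families and similar desk-scale gene sets.
    Infers exon/intron structure by spliced alignment of a CDS against its
    genomic region, computes intron phases, back-translates a protein
    alignment into a codon alignment, projects intron positions onto
    alignment coordinates, detects shared intron positions under a strict
    positional-identity rule, tabulates per-group phase statistics,
    classifies protein domain architectures into a rule-based type system,
    and builds bootstrapped neighbor-joining trees from p-distances with
    pairwise deletion. A gene-family simulator (substitution along a guide
    tree, intron gain and loss, retroposition producing intronless
    paralogs) provides ground-truthed inputs for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
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
    utils
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
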