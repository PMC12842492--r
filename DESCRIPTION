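Package: linkerdock
Title: Sequential Carbohydrate Docking onto Disordered Linkers of
    Bacterial Transcription Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to study low-affinity carbohydrate binding to the
    intrinsically disordered inter-domain linkers of GntR-family
    transcription factors. Implements an empirical pairwise scoring
    function on the AutoDock-Vina functional form, stochastic
    flexible-ligand blind docking, a sequential multi-ligand protocol in
    which each round's best pose is frozen into the receptor, geometric
    hydrogen-bond and ligand-cluster profiling of the resulting
    complexes, and region-aware background statistics that separate
    significant linker or pocket binding from nonspecific surface
    attachment. Ships synthetic generators for conformer ensembles,
    sugar-like ligands and binding-energy tables so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
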