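Package: assemblypath
Title: Assembly-Order Prediction for Multimeric Protein Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the assembly order of multimeric protein complexes.
    Implements two buried-surface-area (BSA) predictors that operate on a
    solved complex (pairwise BSA maximum-spanning-tree assembly and greedy
    subcomplex-transition BSA), and a decoy-ensemble predictor that simulates
    complex assembly with a genetic algorithm over spanning trees of pairwise
    docking poses, inferring the pathway from score-rank orderings of the
    surviving decoys with voting across model populations. Includes
    Shrake-Rupley solvent-accessible surface area, inter-chain contact and
    clash analysis, an assembly-pathway text notation with parser and
    formatter, pathway evaluation metrics (step scores, permutation-minimised
    complex RMSD, largest assembled subcomplex, interface-topology
    comparison), and a synthetic benchmark generator with planted assembly
    orders for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
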