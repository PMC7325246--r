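Package: degronscan
Title: Discovery and Quantification of C-Terminal Degrons in Protein Families
Version: 0.1.0
Authors@R: person("Degronscan", "Developers", role = c("aut", "cre"),
    email = "maintainers@degronscan.org")
Description: Tools for discovering conserved C-terminal degradation signals
    (degrons) in bacterial protein families, with the aldehyde decarbonylase
    degron as the motivating case. Provides sequence family input/output and
    redundancy reduction, pairwise and progressive multiple alignment,
    neighbor-joining phylogeny with bootstrap support and clade-based
    representative selection, terminal-residue frequency profiling and
    threshold consensus calling, degron-likeness scoring against a bundled
    reference catalogue, and quantification of reporter-fluorescence
    degradation time courses (OD-normalized percent-of-control, decay-rate
    fitting, fold-change arithmetic). A seeded synthetic-data module
    generates sequence families with a planted differentially conserved
    terminal motif and reporter time courses with known kinetics, so every
    pipeline stage is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
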