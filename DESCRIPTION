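Package: mutsolv
Title: Mutation-Induced Solvation and Core-Packing Analysis of MD Ensembles
Version: 0.1.0
Authors@R: person("Analysis", "Pipeline", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Trajectory analysis for comparing wild-type and point-mutant
    protein ensembles from molecular dynamics: Kabsch-superposition RMSD
    time series, Shrake-Rupley solvent-accessible surface area
    distributions for the residue neighborhood of a mutation site,
    per-residue radial distribution functions of water with a cumulative
    RDF-difference ranking statistic, and hydrophobic-core
    radius-of-gyration distributions. Includes readers and writers for
    multi-model PDB and DCD trajectories, a deterministic synthetic
    solvated mini-protein generator with planted ground truth for
    validation, and a command-line pipeline that produces a
    machine-readable comparison report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
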