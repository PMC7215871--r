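Package: diccr
Title: Distance-Correlation Analysis of Multi-Domain Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for quantifying concerted inter-domain motion in molecular
    dynamics trajectories of multi-domain proteins. Computes distance
    correlation coefficients (DiCC) between domain position series from
    double-centered pairwise-distance matrices, assembles domain-by-domain
    DiCC matrices and their absolute differences between two conditions
    (e.g. wild type versus a point mutant), performs Kabsch rigid-body
    superposition and per-domain backbone RMSD series, tracks ligand
    translocation via atom-pair distance series and net centroid
    displacement, detects contact shells and geometric hydrogen-bond
    networks, and generates synthetic correlated multi-domain trajectories
    with prescribed inter-domain coupling for validation. Reads and writes
    PDB structures, multi-model PDB and CHARMM/NAMD-dialect DCD
    trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
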