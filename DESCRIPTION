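Package: pocketdock
Title: Protein-Ligand Docking with Empirical Scoring and Random-Forest Rescoring
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale protein-ligand docking engine and benchmark toolkit.
    Parses PDBQT receptors and torsion-tree ligands with automatic deactivation
    of hydrogen-only torsions, scores poses with a five-term empirical function
    (two gaussians, repulsion, hydrophobic and hydrogen-bond ramps) served from
    precalculated pair-potential tables and per-atom-type grid maps, searches
    the pose space by Monte Carlo with BFGS quasi-Newton local optimization
    under the Metropolis criterion, and re-scores docked poses with a
    random-forest regression on 36 protein-ligand element-pair contact counts.
    Includes benchmark machinery (automatic search-box definition, RMSD
    success-rate tables, correlation metrics, nine-descriptor ligand filtering)
    and programmatic fixture generators so the whole pipeline is testable
    without external datasets.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
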