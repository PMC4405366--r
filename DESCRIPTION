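Package: idpens
Title: Conformational Ensemble Analysis for Intrinsically Disordered Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing heterogeneous conformational ensembles of
    intrinsically disordered proteins such as the p53 transactivation domain.
    Reads and writes multi-model PDB ensembles; computes per-residue helicity
    profiles, helical-substate distributions, long-range contact-probability
    maps, inter-residue distance distributions and radii of gyration;
    back-calculates paramagnetic relaxation enhancement (PRE) intensity-ratio
    profiles for site-directed spin labels; performs fixed-radius
    conformational clustering on superposed C-alpha RMSD; and reports
    ensemble convergence diagnostics and wild-type versus mutant comparisons.
    A seeded helix-coil Monte Carlo generator produces C-alpha-trace (or
    N-CA-C backbone) ensembles with known ground-truth helicity and biased
    long-range contacts for validation of every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    graphics,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
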