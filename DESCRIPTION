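Package: ifacemd
Title: Interface Contact and Stability Analysis for Protein Complex Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometric detection of hydrogen bonds and salt bridges across a
    two-domain protein-protein interface in molecular dynamics trajectories,
    with per-residue-pair survival-ratio statistics, replicate aggregation
    (mean and SEM), thermal-stability classification and key-residue
    prediction.  Also provides structural stability metrics (Kabsch
    superposition RMSD, Shrake-Rupley solvent accessible surface area and
    interface burial, a switched Lennard-Jones plus Coulomb interaction
    energy), Gaussian fitting of interface hydrogen-bond counts, triage of
    docked complex models against interface-composition criteria, and a
    deterministic synthetic trajectory generator with programmed per-pair
    bond occupancies for validating every stage at desk scale.  Developed
    around the ADAMTS13 TSP8-Spacer complex but applicable to any two-domain
    interface.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
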