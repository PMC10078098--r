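Package: consensusVS
Title: Consensus Virtual Screening for Colchicine-Site Tubulin Inhibitors
Version: 0.1.0
Authors@R: person("DIFACQUIM-style", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reusable consensus virtual-screening pipeline for
    colchicine-site tubulin-microtubule inhibitors: dual-fingerprint Tanimoto
    similarity screening with median-plus-one-standard-deviation consensus
    thresholds, ligand-efficiency normalisation and filtering of external
    docking scores, consensus pharmacophore construction and matching from
    docked binding modes, deterministic rule-based ADMET and pan-assay
    interference filtering, key binding-site residue contact analysis over
    multi-frame ensembles, extended-connectivity interaction features (ECIF)
    with a pluggable affinity regressor, and Bemis-Murcko scaffold-diverse
    hit selection. Includes a native chemistry core (SMILES/SDF/PDB parsing,
    fingerprints, scaffolds, substructure search) and a synthetic-fixture
    generator with planted ground truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
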