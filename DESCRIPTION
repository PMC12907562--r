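Package: clampconf
Title: Conformational Energetics of Peptide Ligands on the 9-1-1 DNA Clamp
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for identifying stable ligand-binding conformations of
    short peptides on PCNA-like DNA-damage clamps from ensembles of
    residue-level pair-interaction-energy (PIE) matrices and coordinate
    trajectories. Conformations are fingerprinted by their PIE matrices,
    grouped by agglomerative hierarchical clustering, and ranked by total
    interaction energy; the most stable cluster is selected with
    Tukey-Kramer multiple comparisons and a compact-letter display, with
    iterative re-seeded refinement and cluster-lineage naming. Includes
    per-residue PIEDA component decomposition and interaction-character
    classification, simulated-annealing schedule and sampling bookkeeping,
    Kabsch superposition, per-residue RMSF, Shrake-Rupley solvent-accessible
    surface area and buried interface area, binding-free-energy
    state-transition ledgers, a position-frequency profile of the KYxxL+
    Rad9-binding motif with consensus-pattern and log-odds scanning, and a
    synthetic-data module that generates cluster-structured PIE ensembles,
    coordinate ensembles with prescribed fluctuations, and motif-bearing
    sequences with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
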