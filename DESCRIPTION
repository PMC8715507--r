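Package: rotamerfit
Title: Protein Side-Chain Chi1 Rotamers from Vicinal J Couplings
Version: 0.1.0
Authors@R:
    person("rotamerfit", "developers", email = "rotamerfit@example.org",
           role = c("aut", "cre"))
Description: Tools for determining protein side-chain chi1 conformations from
    vicinal three-bond spin-spin coupling constants (3J, Hz). Fits extended
    Karplus (Fourier) equations to dihedral-scan coupling tables, infers chi1
    angles and staggered-rotamer populations under three static models
    (unimodal, trimodal-staggered, trimodal-trigonal), classifies residues as
    unimodal or trimodal, and validates predictions against NMR- and
    X-ray-derived angles with circular statistics. Ships reference chi1 tables
    for the Val, Leu and Ile residues of Desulfovibrio vulgaris flavodoxin, a
    synthetic-data generator with known ground truth, chi1 extraction from PDB
    coordinates, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
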