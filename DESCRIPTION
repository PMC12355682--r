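Package: qmmmtools
Title: QM/MM Boundary Construction, Charge-Redistribution Schemes and
    Embedding Energy Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the boundary machinery of combined quantum-mechanics /
    molecular-mechanics (QM/MM) calculations on proteins: detection and shell
    classification of covalent junctions between the QM and MM regions,
    hydrogen link-atom placement, construction of the external point-charge
    model under ten charge-redistribution schemes (Z0-Z3, DZ1-DZ3, ZZ2, RCD
    and charge-shift), additive and subtractive energy assembly with
    mechanical or electrostatic embedding against a pluggable QM backend
    (a deterministic classical surrogate ships with the package), and big-QM
    region selection with junction relocation, backbone spans, solvent
    exposure classification and neutralization of solvent-exposed charged
    residues. Includes a minimal pairwise molecular-mechanics evaluator, a
    deterministic synthetic-fixture generator, readers for PDB and an AMBER
    prmtop subset, a JSON topology dialect, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    jsonlite,
    generics,
    ggplot2,
    bio3d,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
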