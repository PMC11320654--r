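Package: confshift
Title: Conformational Analysis of Solution Structures from Calculated NMR Chemical Shifts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Selects the solution conformation, or conformer mixture, of an
    organic molecule by confronting per-conformer quantum-chemical NMR
    shielding calculations with experimental 1H and 13C chemical shifts.
    Implements DP4+ probabilities with Student-t error models over scaled
    and unscaled shift errors, corrected mean absolute and maximum errors
    (CMAE, CMaxErr), Boltzmann populations from DFT energies, Kabsch
    superposition RMSD with hierarchical conformer clustering, a molar
    fraction simplex-grid DP4+ scan over conformer mixtures with ternary
    aggregation, and ensemble-averaged 3JHH coupling comparison. Readers
    are provided for multi-structure XYZ files, Gaussian-style quantum
    chemistry logs, and delimited shift, shielding, and coupling tables.
    A synthetic-study generator with known ground-truth mixtures supports
    validation of the whole pipeline without any quantum-chemistry run.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d
Config/testthat/edition: 3
RoxygenNote: 7.3.3
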