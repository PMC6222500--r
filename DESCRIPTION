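Package: amidescan
Title: Steric Effects and Cis/Trans Isomerization Analytics for Secondary Amides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis layer for quantum-chemical studies of cis/trans
    isomerization in secondary amides on a dipeptide-ester scaffold.
    Provides group-additivity estimation of steric energies from
    tert-butyl substitution increments, cis-versus-trans energetics and
    effective rotation-barrier selection, amide geometry analytics
    (backbone dihedrals, planarity classification, hydrogen-bond
    criterion, rigid superposition), a three-round directional
    relaxed-coordinate-scan driver over pluggable torsional energy
    backends with syn/anti barrier-geometry classification, and
    synthetic-data generators (Fourier torsion potentials, additive
    energy tables with injected steric offsets, idealized backbone
    fragments) with dense-grid ground truth for validation. Ships the
    study's conformer-energy, dihedral and barrier tables as plain-text
    fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    jsonlite,
    withr
Config/testthat/edition: 3
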