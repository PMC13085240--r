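Package: qmembed
Title: QM/MM Model Building: QM-Region Selection, Composite Energies, and
    Projection-Based Embedding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for constructing multiscale QM/MM models of enzyme
    reactions. Implements a topologically extended, distance-based QM-region
    selection algorithm over molecular bond graphs (cut rules at apolar
    carbon-carbon bonds, hydrogen link-atom placement, shared-link merging,
    aliphatic fragment pruning, multi-structure union, residue exclusion
    scans), composite energy assembly for reaction profiles (two-point
    complete-basis-set extrapolation of Hartree-Fock and correlation
    energies, local-approximation-free extrapolation with uncertainty
    bands, coupled-cluster corrections evaluated at reduced QM size, and
    QM-size convergence reports), and a desk-scale restricted Hartree-Fock
    engine for Huzinaga projection-based QM-in-QM embedding on toy model
    Hamiltonians, including Pipek-Mezey orbital localization, Mulliken
    active-orbital selection, atomic-orbital basis truncation, and a
    subtractive ONIOM comparator. Seeded generators supply protein-like
    topologies, model Hamiltonians, and size-convergent energy tables for
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
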