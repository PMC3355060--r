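Package: penet
Title: Protein Energy Networks and Family-Level Interaction Conservation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds protein energy networks (PENs): residue interaction graphs
    whose edges carry pairwise non-bonded interaction energies (Coulomb plus
    Lennard-Jones) averaged over a conformational ensemble. Thresholded,
    unweighted networks at an energy cutoff support cluster, hub and
    largest-cluster transition analyses and secondary-structure interface
    classification. Member networks of a protein family are remapped onto a
    multiple structure-based sequence alignment with virtual nodes at gap
    positions, yielding family networks with per-edge commonality
    coefficients, entropy-based residue conservation indices, and an
    interaction-conservation phylogeny that clusters remote homologues by
    shared network edges rather than sequence identity. A seeded synthetic
    fixture generator produces toy structures with analytically known
    energies and families of energy matrices with planted conserved edges,
    gaps and clade structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    Biostrings,
    ape,
    bio3d,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'conservation.R'
    'energy-model.R'
    'family-alignment.R'
    'io.R'
    'pen-core.R'
    'phylogeny.R'
    'synthetic.R'
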