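Package: hydromaps
Title: Backbone-Dependent 3D Hydropathic Interaction Maps for Protein and
    Protein-Lipid Structures
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Deconstructs protein and protein-lipid structures into
    per-residue, backbone-conformation-binned three-dimensional hydropathic
    interaction maps. Residue sidechains are scored against their environment
    with a logP-based (HINT-style) atom-pair function, deposited onto 0.5
    Angstrom grids in a canonical residue frame, clustered per Ramachandran
    "chess square" and chi-parse bin with gap-statistic k selection, and
    summarised by solvent- and lipid-accessible surface area (SASA/LASA) and
    four-class interaction character. Residue-level cluster maps can be
    reassembled into protein-frame composite maps and score grids for
    sidechain-assignment optimisation. Includes a synthetic helical-bundle
    membrane fixture generator emulating bilayer-annotated inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, bio3d, cluster, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
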