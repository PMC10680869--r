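Package: chipacker
Title: Two-Stage Protein Side-Chain Packing with Rotationally
    Equivariant Holographic Encodings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts protein side-chain conformations by regressing the
    side-chain chi dihedral angles with SO(3)-equivariant neural networks
    that operate on 3D Zernike (holographic) encodings of residue-centred
    atomic neighborhoods, then rebuilds full-atom side chains from the
    predicted chi angles and median redundant internal coordinates.
    Includes the geometry layer (dihedral computation, internal-coordinate
    atom placement, symmetry-aware RMSD), the steerable encoding and
    network layers, the periodic-angle training objectives, a two-stage
    initial-guess/refinement packing pipeline, and a deterministic
    generator of synthetic structures for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
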