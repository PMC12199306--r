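Package: hsr
Title: Hypershape Recognition for Moment-Based Molecular Similarity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Moment-based 3D molecular similarity with deterministic,
    PCA-derived reference frames. Molecules are represented as N-dimensional
    point clouds ("hypershapes") built from Cartesian coordinates plus
    per-atom numerical features (atomic number, isotope, formal charge, or
    any user-supplied values). A sign-oriented principal-component frame
    yields N+1 reference points, a 3(N+1)-moment fingerprint, and an
    inverse scaled-Manhattan similarity score, with optional
    determinant-based enantiomer discrimination. Includes the
    heuristic-reference baselines USR, CSR and USR:OptIso, subset
    (USRCAT-style) and partial-charge (ElectroShape-style) emulation modes,
    readers and writers for SDF (MOL V2000), XYZ and PDB structures, and a
    seedable synthetic-fixture generator for chiral, symmetric and
    isotope-labelled test systems.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ChemmineR,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
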