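Package: growkit
Title: Constrained R-Group Growth and Pose Refinement in Rigid Protein Pockets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Grows user-chosen R-groups from a fixed ligand core inside a rigid
    protein pocket. Enumerates core-constrained conformers, refines them under a
    hybrid mechanical-embedding potential with scaled receptor-ligand
    electrostatics and Lennard-Jones terms, filters steric clashes and
    drug-likeness liabilities, re-scores poses through an external scorer
    contract, and writes structures and atom maps ready for relative binding
    free energy calculations.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    bio3d,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
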