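Package: molkit
Title: Molecular Structures, Sequences and Density Maps with a Selection
    Query Language
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrated toolkit for computational structural biology:
    a handle/view data model for molecular structures with a Boolean
    selection mini-language (including proximity queries), rule-based and
    heuristic bond connectivity, PDB and CHARMM DCD input/output with
    configurable IO profiles and lazy trajectory access, gapped sequence
    and alignment containers with efficient gap-list index mapping and
    structure attachment, Needleman-Wunsch and Smith-Waterman pairwise
    alignment with affine gaps, column conservation scoring, Kabsch
    least-squares superposition, and domain-aware image handles for
    electron density maps with Fourier filtering, structure-to-density
    conversion, real-space cross-correlation and MRC/CCP4 input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    bio3d
Config/testthat/edition: 3
RoxygenNote: 7.3.3
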