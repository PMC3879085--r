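Package: pdbkit
Title: Parse, Traverse, Transform and Write Protein Data Bank Structures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A column-exact codec and hierarchical toolkit for legacy
    Protein Data Bank (PDB) coordinate files. Decodes and re-encodes
    ATOM/HETATM/TER/MODEL/ENDMDL records at their fixed columns, collects
    strict-format violations as data instead of aborting, and assembles a
    Structure -> Model -> Chain -> Residue -> Atom hierarchy. A generic
    typed-traversal layer (count, map, fold, stateful map over any contained
    level) supports the included analyses: splitting multi-model entries,
    recentering, residue and atom renumbering with TER counting, radius of
    gyration, canonical-axes reorientation, one-letter sequence extraction
    and strict-format normalization. Includes a deterministic synthetic
    fixture generator, a serial/parallel parser with identical results, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, parallel, Biostrings
Suggests: testthat (>= 3.0.0), bio3d, jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'pdbkit-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'codec.R'
    'parser.R'
    'writer.R'
    'traversal.R'
    'analysis.R'
    'fixtures.R'
    'cli.R'
    'utils.R'
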