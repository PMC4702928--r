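Package: dpimodes
Title: Interaction Modes and Classes of Protein Domain-DNA Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects atomic contacts between protein structural elements
    (helix, strand, loop) and double-helical DNA elements (backbone, major
    groove, minor groove) in protein-DNA complex structures.  Hydrogen bonds
    are scored by a distance and covalent-geometry criterion; hydrophobic
    contacts require proximity, an unobstructed line of sight and shared
    membership in a hydrophobic cluster.  Per-structure contact-type sets
    (interaction modes) are aggregated into per-family interaction classes
    as the intersection of per-domain unions.  DNA shape parameters
    (axis bend, groove width and depth) are computed in domain contact
    zones.  Includes a synthetic-complex generator (ideal fiber B-DNA plus
    placed peptide probes) so the full pipeline is testable without
    structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
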