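Package: hydroRIN
Title: Water-Inclusive Residue Interaction Network Centrality Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds residue interaction networks (RINs) from protein-complex
    structures with or without crystallographic water molecules as nodes, and
    quantifies how water inclusion changes the set of central residues.
    Contact graphs are derived from heavy-atom distances (5 Angstrom for
    residue-residue contacts, 3.5 Angstrom for water contacts); node
    importance is scored by residue centrality analysis (change in average
    shortest path length upon node removal) and betweenness centrality
    analysis, each standardized to network-wide Z-scores. Includes interface
    annotation, interface-water network variants, water-removal experiments,
    a differential wet-versus-dry report, and a deterministic generator of
    synthetic two-chain complexes with water shells for testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
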